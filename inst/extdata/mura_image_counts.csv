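region,split,abnormal,normal
Elbow,train,1734,2584
Elbow,validation,272,341
Elbow,test,230,235
Finger,train,1710,2750
Finger,validation,258,388
Finger,test,247,214
Forearm,train,583,1042
Forearm,validation,78,122
Forearm,test,151,150
Hand,train,1287,3549
Hand,validation,197,510
Hand,test,189,271
Humerus,train,514,593
Humerus,validation,85,80
Humerus,test,140,148
Shoulder,train,3627,3673
Shoulder,validation,541,538
Shoulder,test,278,285
Wrist,train,3489,4993
Wrist,validation,498,772
Wrist,test,295,364
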