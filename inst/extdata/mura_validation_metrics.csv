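model,region,auc,accuracy,kappa
convnet,Elbow,0.90,0.85,0.73
convnet,Finger,0.90,0.83,0.64
convnet,Forearm,0.85,0.84,0.64
convnet,Hand,0.84,0.78,0.52
convnet,Humerus,0.91,0.83,0.68
convnet,Shoulder,0.84,0.79,0.58
convnet,Wrist,0.92,0.87,0.77
resnet,Elbow,0.91,0.84,0.67
resnet,Finger,0.93,0.87,0.68
resnet,Forearm,0.88,0.85,0.67
resnet,Hand,0.86,0.82,0.60
resnet,Humerus,0.96,0.90,0.85
resnet,Shoulder,0.89,0.84,0.71
resnet,Wrist,0.96,0.91,0.80
densenet,Elbow,0.93,0.88,0.80
densenet,Finger,0.92,0.84,0.65
densenet,Forearm,0.90,0.86,0.70
densenet,Hand,0.85,0.82,0.59
densenet,Humerus,0.95,0.88,0.75
densenet,Shoulder,0.86,0.82,0.63
densenet,Wrist,0.95,0.89,0.77
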