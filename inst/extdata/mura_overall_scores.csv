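model,metric,score
convnet,auc,0.88
resnet,auc,0.92
densenet,auc,0.91
res_dense,auc,0.93
calibrated,auc,0.93
convnet,accuracy,0.82
resnet,accuracy,0.86
densenet,accuracy,0.85
res_dense,accuracy,0.86
calibrated,accuracy,0.87
convnet,precision,0.86
resnet,precision,0.91
densenet,precision,0.90
res_dense,precision,0.91
calibrated,precision,0.93
convnet,recall,0.72
resnet,recall,0.78
densenet,recall,0.76
res_dense,recall,0.77
calibrated,recall,0.81
convnet,kappa,0.63
resnet,kappa,0.71
densenet,kappa,0.70
res_dense,kappa,0.72
calibrated,kappa,0.74
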