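method,class,accuracy,sensitivity,precision,reported_oa,reported_os,reported_op,time_ms
transfer_learning,AMD,90.90,68.37,89.40,79.41,76.25,84.01,6.82
transfer_learning,DME,81.45,76.88,79.10,79.41,76.25,84.01,6.82
transfer_learning,Normal,86.47,83.49,83.54,79.41,76.25,84.01,6.82
vgg16,AMD,92.76,77.12,86.90,83.69,81.96,85.20,1.30
vgg16,DME,84.83,79.76,81.23,83.69,81.96,85.20,1.30
vgg16,Normal,89.79,88.99,87.45,83.69,81.96,85.20,1.30
resnet,AMD,92.35,71.73,90.28,84.55,82.13,86.92,4.02
resnet,DME,87.48,81.41,86.12,84.55,82.13,86.92,4.02
resnet,Normal,89.28,93.26,84.36,84.55,82.13,86.92,4.02
ifcnn,AMD,92.46,71.71,92.49,84.62,81.86,87.47,1.60
ifcnn,DME,86.54,82.09,83.10,84.62,81.86,87.47,1.60
ifcnn,Normal,90.24,91.78,86.82,84.62,81.86,87.47,1.60
hctnet,AMD,95.94,82.60,95.08,86.18,85.40,88.53,3.81
hctnet,DME,86.61,80.22,85.29,86.18,85.40,88.53,3.81
hctnet,Normal,89.81,93.39,85.22,86.18,85.40,88.53,3.81
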