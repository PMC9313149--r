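method,class,accuracy,sensitivity,precision,reported_oa,reported_os,reported_op,time_ms
transfer_learning,CNV,83.86,92.64,76.52,76.26,57.34,73.47,6.31
transfer_learning,DME,89.53,36.00,74.61,76.26,57.34,73.47,6.31
transfer_learning,Drusen,90.13,18.56,65.22,76.26,57.34,73.47,6.31
transfer_learning,Normal,88.99,92.18,77.55,76.26,57.34,73.47,6.31
vgg16,CNV,92.92,91.37,92.83,86.68,79.79,81.29,1.08
vgg16,DME,94.20,78.79,78.43,86.68,79.79,81.29,1.08
vgg16,Drusen,92.34,55.45,65.89,86.68,79.79,81.29,1.08
vgg16,Normal,93.90,93.57,88.02,86.68,79.79,81.29,1.08
resnet,CNV,93.74,90.92,94.92,89.87,86.11,85.82,3.92
resnet,DME,95.88,85.23,84.60,89.87,86.11,85.82,3.92
resnet,Drusen,94.36,72.21,72.74,89.87,86.11,85.82,3.92
resnet,Normal,95.75,96.08,91.01,89.87,86.11,85.82,3.92
ifcnn,CNV,93.45,91.09,94.16,88.67,83.84,84.42,1.46
ifcnn,DME,95.06,83.68,80.97,88.67,83.84,84.42,1.46
ifcnn,Drusen,93.95,65.80,72.92,88.67,83.84,84.42,1.46
ifcnn,Normal,94.80,94.78,89.63,88.67,83.84,84.42,1.46
hctnet,CNV,94.60,92.23,95.53,91.56,88.57,88.11,3.74
hctnet,DME,96.14,87.96,84.42,91.56,88.57,88.11,3.74
hctnet,Drusen,95.54,77.36,79.00,91.56,88.57,88.11,3.74
hctnet,Normal,96.84,96.73,93.50,91.56,88.57,88.11,3.74
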