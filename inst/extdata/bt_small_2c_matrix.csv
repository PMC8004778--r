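extractor,fc,gaussian_nb,adaboost,knn,rf,svm_linear,svm_sigmoid,svm_rbf,elm
resnet50,0.9216,0.8431,0.8431,0.8627,0.8824,0.8235,0.8824,0.9020,0.9020
resnet101,0.9216,0.8824,0.8431,0.8235,0.9020,0.8235,0.8824,0.9020,0.8824
densenet121,0.9216,0.7647,0.8235,0.9216,0.8824,0.8431,0.8824,0.8627,0.9020
densenet169,0.9608,0.8039,0.8627,0.9020,0.9412,0.9608,0.9608,0.9804,0.9412
vgg16,0.8431,0.7451,0.7451,0.7059,0.8431,0.8627,0.8627,0.8039,0.8039
vgg19,0.8235,0.6863,0.7843,0.6863,0.8235,0.8235,0.8235,0.8235,0.9020
alexnet,0.9216,0.7255,0.8431,0.7843,0.9020,0.8235,0.8627,0.9020,0.9020
inception_v3,0.9216,0.8824,0.9020,0.8235,0.9412,0.9020,0.9020,0.9020,0.9020
resnext50,0.9412,0.9020,0.9020,0.9020,0.9216,0.9216,0.9216,0.9216,0.9216
resnext101,0.9216,0.8039,0.8235,0.8235,0.9020,0.8627,0.9020,0.9216,0.9216
shufflenet_v2,0.8431,0.7647,0.9216,0.8627,0.9020,0.9412,0.9412,0.9412,0.9412
mobilenet_v2,0.8824,0.8431,0.7843,0.8431,0.8824,0.8627,0.8824,0.8824,0.8627
mnasnet,0.9216,0.7843,0.8235,0.8235,0.9216,0.8431,0.8627,0.8627,0.9020
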