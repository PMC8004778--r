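extractor,fc,gaussian_nb,adaboost,knn,rf,svm_linear,svm_sigmoid,svm_rbf,elm
resnet50,0.8760,0.6937,0.6570,0.8576,0.8530,0.8744,0.8760,0.8989,0.8591
resnet101,0.8867,0.7228,0.6799,0.8438,0.8499,0.8897,0.8897,0.9081,0.8683
densenet121,0.8913,0.7106,0.7198,0.8943,0.8744,0.8698,0.8729,0.9158,0.8760
densenet169,0.8959,0.7228,0.7335,0.8821,0.8652,0.8652,0.8729,0.9204,0.8806
vgg16,0.8760,0.6677,0.7106,0.8331,0.8300,0.8606,0.8606,0.8744,0.8423
vgg19,0.8683,0.5942,0.6309,0.8346,0.8377,0.8606,0.8606,0.8790,0.8453
alexnet,0.8637,0.6340,0.6554,0.8714,0.8453,0.8652,0.8683,0.9066,0.8361
inception_v3,0.8652,0.6708,0.6830,0.8300,0.8132,0.8591,0.8591,0.8867,0.8438
resnext50,0.8744,0.7152,0.6891,0.8775,0.8346,0.8560,0.8576,0.8959,0.8560
resnext101,0.8851,0.6692,0.7198,0.8714,0.8346,0.8744,0.8744,0.8989,0.8744
shufflenet_v2,0.8637,0.7152,0.7381,0.8637,0.8576,0.8989,0.8989,0.9112,0.8606
mobilenet_v2,0.8928,0.6983,0.7136,0.8897,0.8423,0.8851,0.8851,0.9158,0.8729
mnasnet,0.8851,0.6922,0.7458,0.8928,0.8515,0.8959,0.8959,0.9127,0.8775
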