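extractor,fc,gaussian_nb,adaboost,knn,rf,svm_linear,svm_sigmoid,svm_rbf,elm
resnet50,0.9767,0.8117,0.9600,0.9767,0.9400,0.9750,0.9750,0.9817,0.9667
resnet101,0.9767,0.8250,0.9433,0.9733,0.9567,0.9750,0.9733,0.9800,0.9717
densenet121,0.9750,0.8383,0.9600,0.9817,0.9683,0.9683,0.9683,0.9833,0.9817
densenet169,0.9750,0.8400,0.9650,0.9783,0.9633,0.9667,0.9650,0.9800,0.9800
vgg16,0.9550,0.7383,0.8833,0.9617,0.9283,0.9517,0.9500,0.9650,0.9550
vgg19,0.9550,0.7067,0.8850,0.9600,0.9300,0.9550,0.9550,0.9633,0.9450
alexnet,0.9633,0.7067,0.9200,0.9550,0.9500,0.9400,0.9500,0.9750,0.9633
inception_v3,0.9817,0.8317,0.9567,0.9800,0.9567,0.9750,0.9733,0.9883,0.9800
resnext50,0.9717,0.8600,0.9550,0.9817,0.9550,0.9700,0.9683,0.9833,0.9750
resnext101,0.9783,0.8583,0.9633,0.9833,0.9617,0.9717,0.9717,0.9817,0.9817
shufflenet_v2,0.9433,0.8533,0.9533,0.9700,0.9517,0.9617,0.9617,0.9783,0.9700
mobilenet_v2,0.9667,0.8400,0.9367,0.9700,0.9450,0.9617,0.9617,0.9783,0.9633
mnasnet,0.9817,0.8550,0.9467,0.9750,0.9567,0.9700,0.9733,0.9817,0.9833
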