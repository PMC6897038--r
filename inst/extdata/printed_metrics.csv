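classifier,features,metric,printed
SVM,ExHOG_CNN,accuracy,95.32
SVM,HOG_CNN,accuracy,95.15
SVM,CNN_LBP,accuracy,95.15
KNN,HOG,accuracy,94.15
RF,HOG,accuracy,94.65
RF,ExHOG,accuracy,90.64
DT,ExHOG,accuracy,88.3
SVM,HOG_CNN,kappa,85.78
SVM,CNN_LBP,kappa,85.78
RF,HOG,kappa,82.9
SVM,ExHOG_CNN,fscore,97
SVM,HOG_CNN,fscore,96.9
SVM,CNN_LBP,fscore,96.9
SVM,CNN,fscore,65.78
KNN,HOG,recall,99.78
RF,ExHOG,sensitivity,99.78
SVM,ExHOG_CNN,precision,97.23
SVM,LBP,ppv,92
SVM,CNN,ppv,91.8
SVM,HOG_CNN,ppv,97
SVM,ExHOG,ppv,96.5
SVM,HOG_CNN_LBP,ppv,93
SVM,LBP,npv,79.3
SVM,CNN,npv,65.64
SVM,ExHOG,npv,80.15
SVM,HOG_CNN_LBP,npv,81.6
SVM,ExHOG_CNN,specificity,95.03
RF,ExHOG,specificity,57.95
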