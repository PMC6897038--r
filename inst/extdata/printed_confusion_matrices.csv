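classifier,features,tp,fp,fn,tn
SVM,LBP,430,37,27,104
SVM,CNN,429,38,45,86
SVM,ExHOG,451,16,26,105
SVM,HOG,453,14,20,111
SVM,HOG_CNN,453,14,15,116
SVM,HOG_CNN_LBP,435,32,24,107
SVM,ExHOG_CNN_LBP,434,33,24,107
SVM,CNN_LBP,453,14,15,116
SVM,ExHOG_CNN,452,15,13,118
RF,LBP,464,3,41,90
RF,CNN,448,19,23,108
RF,ExHOG,466,1,55,76
RF,HOG,464,3,29,102
RF,HOG_CNN,456,11,28,103
RF,HOG_CNN_LBP,435,32,24,107
RF,ExHOG_CNN_LBP,457,10,29,102
RF,CNN_LBP,453,14,20,111
RF,ExHOG_CNN,456,11,33,98
DT,LBP,424,43,31,100
DT,CNN,422,45,33,98
DT,ExHOG,423,44,26,105
DT,HOG,422,45,27,104
DT,HOG_CNN,424,43,34,97
DT,HOG_CNN_LBP,429,38,37,94
DT,ExHOG_CNN_LBP,417,50,35,96
DT,CNN_LBP,418,49,35,96
DT,ExHOG_CNN,418,49,35,96
KNN,LBP,449,18,33,98
KNN,CNN,431,36,24,107
KNN,ExHOG,451,16,24,107
KNN,HOG,466,1,34,97
KNN,HOG_CNN,445,12,29,102
KNN,HOG_CNN_LBP,449,18,33,98
KNN,ExHOG_CNN_LBP,449,18,33,98
KNN,CNN_LBP,443,24,26,105
KNN,ExHOG_CNN,451,16,24,107
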