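dataset,kboost,smoteboost,rusboost,smote_boosted
Wbcd,0.956,0.924,0.886,0.847
Bcwo,0.936,0.839,0.8539,0.8756
Abalone,0.299,0.264,0.15,0.232
Pima,0.454,0.432,0.446,0.425
Redwine1,0.446,0.397,0.34,0.377
Redwine2,0.712,0.59,0.577,0.691
Redwine3,0.194,0.054,0.171,0.137
Redwine4,0.38,0.317,0.152,0.232
Whitewine,0.625,0.502,0.49,0.593
Yeast1,0.898,0.497,0.552,0.45
Yeast2,0.855,0.836,0.824,0.821
Yeast3,0.28,0.232,0.27,0.195
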