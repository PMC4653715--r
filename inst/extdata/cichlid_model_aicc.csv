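variable,model,logl,aicc,daicc,weight
PC1,BM,77.53,-150.81,5.20,0.017
PC1,OU,81.11,-155.71,0.29,0.193
PC1,WN,80.13,-156.00,0.00,0.224
PC1,delta,81.13,-155.74,0.26,0.197
PC1,EB,81.11,-155.71,0.29,0.194
PC1,lambda,,-155.52,0.49,0.175
PC2,BM,92.59,-180.93,4.97,0.021
PC2,OU,96.09,-185.68,0.22,0.231
PC2,WN,92.57,-180.90,4.99,0.021
PC2,delta,96.13,-185.74,0.16,0.238
PC2,EB,96.10,-185.68,0.22,0.230
PC2,lambda,,-185.90,0.00,0.258
PC3,BM,105.25,-206.25,1.91,0.134
PC3,OU,105.42,-204.33,3.82,0.051
PC3,WN,105.27,-206.30,1.86,0.137
PC3,delta,107.33,-208.16,0.00,0.347
PC3,EB,107.14,-207.77,0.39,0.286
PC3,lambda,,-204.10,4.06,0.046
CS,BM,26.24,-48.22,1.66,0.106
CS,OU,28.10,-49.70,0.19,0.222
CS,WN,24.50,-44.75,5.13,0.019
CS,delta,28.20,-49.88,0.00,0.244
CS,EB,28.10,-49.70,0.19,0.223
CS,lambda,,-49.36,0.53,0.187
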