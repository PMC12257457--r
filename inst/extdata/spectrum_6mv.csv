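energy_mev,weight
0.25,7.765039e-02
0.50,9.941712e-02
0.75,1.040691e-01
1.00,1.003172e-01
1.25,9.242913e-02
1.50,8.276225e-02
1.75,7.265936e-02
2.00,6.287565e-02
2.25,5.381283e-02
2.50,4.565755e-02
2.75,3.846662e-02
3.00,3.222052e-02
3.25,2.685732e-02
3.50,2.229402e-02
3.75,1.843993e-02
4.00,1.520463e-02
4.25,1.250267e-02
4.50,1.025595e-02
4.75,8.394776e-03
5.00,6.858026e-03
5.25,5.592786e-03
5.50,4.553728e-03
5.75,3.702348e-03
6.00,3.006161e-03
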