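added_uM,dF_au,sigma_au
1.0000000000000002e-01,3.1156322981915702e-02,4.4721359549995789e-03
1.4002916105333160e-01,5.6933362439283874e-02,4.4721359549995789e-03
1.9608165945299866e-01,6.8044179388674769e-02,4.4721359549995789e-03
2.7457150271148467e-01,8.8667029025004701e-02,4.4721359549995789e-03
3.8448017173841753e-01,1.1364047502080722e-01,4.4721359549995789e-03
5.3838435890171454e-01,1.6369244012583689e-01,4.4721359549995789e-03
7.5389510101242818e-01,1.8922566866620441e-01,4.4721359549995789e-03
1.0556729851698698e+00,2.3425299725939069e-01,4.4721359549995789e-03
1.4782500246000303e+00,2.8291356630223502e-01,4.4721359549995789e-03
2.0699811077180899e+00,3.3284487375190164e-01,4.4721359549995789e-03
2.8985771791001014e+00,3.9569615603358349e-01,4.4721359549995789e-03
4.0588533063771939e+00,4.6135404263722596e-01,4.4721359549995789e-03
5.6835782333053926e+00,5.2538084289209397e-01,4.4721359549995789e-03
7.9586669179073093e+00,5.8602712348907826e-01,4.4721359549995789e-03
1.1144454516174640e+01,6.5192061931060075e-01,4.4721359549995789e-03
1.5605486162969479e+01,7.1938539009918978e-01,4.4721359549995789e-03
2.1852231352299896e+01,7.7155258765403212e-01,4.4721359549995789e-03
3.0599496234058627e+01,8.2786845558923094e-01,4.4721359549995789e-03
4.2848217863098100e+01,8.6044834332197084e-01,4.4721359549995789e-03
6.0000000000000007e+01,8.8977610972011201e-01,4.4721359549995789e-03
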