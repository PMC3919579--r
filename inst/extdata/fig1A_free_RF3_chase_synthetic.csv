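time_s,signal_au
1.0000000000000002e-03,1.0970935088899885e+00
1.0957757835975649e-03,1.1073441483432098e+00
1.2007245679188582e-03,1.1003340588081529e+00
1.3157249042961342e-03,1.0969927295560373e+00
1.4417394880039283e-03,1.0995744560844571e+00
1.5798232172110562e-03,1.1008236536763887e+00
1.7311320237850707e-03,1.0991110750847291e+00
1.8969325498739255e-03,1.0996818067929242e+00
2.0786127512698272e-03,1.1025327351130227e+00
2.2776935163185867e-03,1.0917462122263308e+00
2.4958413976390917e-03,1.1008030086291483e+00
2.7348825632332189e-03,1.0989154026564629e+00
2.9968180837741968e-03,1.0951518338224455e+00
3.2838406840470253e-03,1.0957962314851126e+00
3.5983530987711921e-03,1.1058106509467891e+00
3.9429881864667280e-03,1.0969511446907552e+00
4.3206309697415230e-03,1.0973311128246881e+00
4.7344427865044225e-03,1.0945739115719615e+00
5.1878877542797259e-03,1.0944958153062205e+00
5.6847617691620769e-03,1.0904744721732418e+00
6.2292242821690531e-03,1.0931713043491500e+00
6.8258331189987769e-03,1.0980589646712664e+00
7.4795826346771002e-03,1.0949835287747061e+00
8.1959455224960374e-03,1.0969037480339954e+00
8.9809186272360453e-03,1.0981032768553964e+00
9.8410731461855434e-03,1.1038890466115283e+00
1.0783609638202424e-02,1.1044370498929086e+00
1.1816418301311521e-02,1.1001405876202006e+00
1.2948145023436237e-02,1.0933125862154889e+00
1.4188263759190750e-02,1.0977390018626334e+00
1.5547155838616171e-02,1.0998859935957541e+00
1.7036196871773102e-02,1.1039604715787661e+00
1.8667851976689562e-02,1.1029343076154274e+00
2.0455780127840360e-02,1.0942470766237062e+00
2.2414948498683768e-02,1.1044525613143910e+00
2.4561757755444273e-02,1.0897145743050196e+00
2.6914179351005509e-02,1.0966845468473654e+00
2.9491905968233468e-02,1.0926274554991457e+00
3.2316516372126736e-02,1.0986443123502116e+00
3.5411656050810716e-02,1.0920109016799897e+00
3.8803235157564578e-02,1.0902246396533160e+00
4.2519645410900912e-02,1.0934381090535110e+00
4.6591997768420539e-02,1.0869810756371061e+00
5.1054382864067022e-02,1.0949744664762235e+00
5.5944156388963169e-02,1.0985451025034110e+00
6.1302251804820816e-02,1.0985426105087537e+00
6.7173523007722752e-02,1.0882159156816149e+00
7.3607119810796498e-02,1.0918600028766705e+00
8.0656899389035364e-02,1.0853336350792595e+00
8.8381877130570233e-02,1.0917346330251190e+00
9.6846720668574277e-02,1.0888228453528985e+00
1.0612229122946154e-01,1.0790124836764812e+00
1.1628623682913218e-01,1.0834134268855564e+00
1.2742364228305431e-01,1.0828306325551200e+00
1.3962774147156973e-01,1.0795348671022835e+00
1.5300069782296749e-01,1.0768263647927128e+00
1.6765445954793654e-01,1.0758659347520816e+00
1.8371169678476637e-01,1.0719083741222821e+00
2.0130682850036558e-01,1.0780312510882015e+00
2.2058714774352883e-01,1.0700504073962482e+00
2.4171405467021709e-01,1.0716779906536218e+00
2.6486440766280195e-01,1.0613267149931711e+00
2.9023200385381159e-01,1.0576002403129687e+00
3.1802920144800206e-01,1.0540204554222399e+00
3.4848869742359223e-01,1.0556149038672797e+00
3.8186547549423139e-01,1.0583306825100229e+00
4.1843894063854842e-01,1.0475398112676386e+00
4.5851525806594018e-01,1.0436360961554851e+00
5.0242991619864563e-01,1.0340443672048540e+00
5.5055053512542973e-01,1.0338485742096708e+00
6.0327994403712681e-01,1.0153246489067567e+00
6.6105955340597755e-01,1.0171165305679313e+00
7.2437305013809117e-01,1.0093035807663568e+00
7.9375044663202554e-01,9.9332290464120565e-01
8.6977251763912478e-01,9.9662259603412517e-01
9.5307566206763938e-01,9.8998768541933535e-01
1.0443572304299353e+00,9.6407903922648386e-01
1.1443813625301447e+00,9.5584239424845896e-01
1.2539853842609192e+00,9.4937387061827561e-01
1.3740868170584020e+00,9.4307486706672883e-01
1.5056910586932550e+00,9.2263993828109980e-01
1.6498997996954483e+00,9.0926113995368218e-01
1.8079202458687464e+00,8.9285332640639281e-01
1.9810752240987275e+00,8.6648135841776230e-01
2.1708142560525041e+00,8.5596805268003839e-01
2.3787256924706992e+00,8.3430500191908141e-01
2.6065500096307397e+00,8.0783694589419264e-01
2.8561943792893660e+00,7.8268804073985809e-01
3.1297486340727678e+00,7.6267377113464296e-01
3.4295027619644949e+00,7.4490373638904261e-01
3.7579660763416562e+00,7.0957160638691685e-01
4.1178882220363437e+00,6.8494868272963727e-01
4.5122821932690576e+00,6.6038309627673109e-01
4.9444495561427475e+00,6.2836748262631226e-01
5.4180080868409499e+00,5.9449316354720927e-01
5.9369220568960843e+00,5.6990815514517645e-01
6.5055354190529719e+00,5.3638877719820865e-01
7.1286081715344816e+00,4.8559400923636808e-01
7.8113562051232126e+00,4.6241789947615608e-01
8.5594949666285878e+00,4.2773668424000971e-01
9.3792873042568505e+00,3.9651691231337000e-01
1.0277595895408741e+01,3.5719554324421599e-01
1.1261940695790647e+01,3.3666336329894048e-01
1.2340561890759298e+01,2.9974611515429855e-01
1.3522488875881015e+01,2.7152409645606318e-01
1.4817615844157869e+01,2.4675625694543440e-01
1.6236784612679777e+01,2.1298360038957431e-01
1.7791875382064095e+01,1.9486107516685811e-01
1.9495906188451507e+01,1.7582547311413216e-01
2.1363141880595059e+01,1.5319580848440895e-01
2.3409213534315001e+01,1.5033944066463509e-01
2.5651249303966736e+01,1.3882501113414122e-01
2.8108017806310684e+01,1.2586405537100273e-01
3.0800085237084392e+01,1.1378818733192025e-01
3.3749987535537933e+01,1.0868239589162983e-01
3.6982419038162114e+01,1.1031965436590319e-01
4.0524439200875584e+01,1.0452402914832194e-01
4.4405699120191393e+01,1.0737688991318974e-01
4.8658689749625410e+01,1.0472289263096822e-01
5.3319013889226568e+01,1.0500904794149231e-01
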