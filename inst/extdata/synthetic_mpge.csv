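gene_symbol,log_ratio
G00001,-0.9480907872952162
G00002,-0.34625063816318224
G00003,0.13317905464125765
G00004,1.9157126532204245
G00005,-1.732553372174336
G00006,-0.25163343020005247
G00007,1.2752946521184867
G00008,-0.4188502936678622
G00009,-0.5788783615365574
G00010,-1.9440286172146264
G00011,-0.2291158604391344
G00012,-0.15741613648491315
G00013,1.3315245769020359
G00014,0.2613602983286468
G00015,0.446841097940857
G00016,-0.44793123024739434
G00017,-0.35998479494996777
G00018,-0.331821885488216
G00019,-2.0034608557780578
G00020,0.23522847851153955
G00021,-0.5852219946155998
G00022,0.49580812079888564
G00023,0.24077980560812887
G00024,0.3652253321964829
G00025,0.021395373178645122
G00026,-1.1905985267408823
G00027,-1.5731526854003155
G00028,-0.13473181873036086
G00029,-0.7868869509594071
G00030,-0.381970779686741
G00031,-1.4733631134888785
G00032,-0.8498160313721651
G00033,-0.9092042670292984
G00034,-0.26261019177198874
G00035,-0.3293061850607303
G00036,-1.9047588804471063
G00037,1.4682009728273764
G00038,-2.0228507055488527
G00039,-0.29884637136853537
G00040,1.2900821303644752
G00041,0.21688295239613262
G00042,-0.7658794155563153
G00043,-0.7151192036802819
G00044,-1.845195989432121
G00045,-1.9658842468226623
G00046,-0.5874946374067389
G00047,0.2914930727375151
G00048,-1.5228080552206869
G00049,0.45075543483532726
G00050,-0.8506729048777932
G00051,-0.9932181797968026
G00052,-0.06635558807108334
G00053,0.004926097612127172
G00054,-2.161767743832366
G00055,-0.49592065709128064
G00056,-0.23284825013264326
G00057,0.37262792051144733
G00058,-1.7378787490578702
G00059,0.30931858406836754
G00060,0.39470838811741943
G00061,-0.055429849272232594
G00062,-0.8879506910467725
G00063,0.14234817821001702
G00064,0.6485589573144122
G00065,1.3892334145908505
G00066,0.1425499237010657
G00067,-0.7317971101713685
G00068,1.414330608238436
G00069,-0.5679028151405268
G00070,1.6007839491851175
G00071,-0.9588154588887943
G00072,0.11063358292510095
G00073,0.0459603808497116
G00074,-1.5218358914439563
G00075,-0.6186689931141647
G00076,-0.20084996468022537
G00077,-0.21687428878911255
G00078,0.9001185343633312
G00079,-2.6709241527684147
G00080,1.7057092185836344
G00081,-0.665832203587718
G00082,1.4673483924343156
G00083,-0.0525741817274476
G00084,-1.392238566679812
G00085,0.8945724721822279
G00086,0.5934807398273628
G00087,1.7380885947047524
G00088,-1.9488199575827125
G00089,1.195436869467081
G00090,-1.4470170971047593
G00091,-2.5519363771293104
G00092,0.8575412468977504
G00093,-1.4865514765029921
G00094,0.02916655336857485
G00095,1.39835221319691
G00096,-0.3002616618805989
G00097,-1.983418670390305
G00098,-1.7005266870317757
G00099,-0.7753475774449576
G00100,0.1781281416587139
G00101,1.528943143274038
G00102,-0.8018971977151687
G00103,-0.09326673210409162
G00104,-1.4148131281894272
G00105,0.6565049269400519
G00106,-0.04947046722995698
G00107,1.467939694873185
G00108,-2.010954901546715
G00109,-0.8282377416128808
G00110,-1.3097274911264272
G00111,-2.2354308238437373
G00112,-0.11093861871623188
G00113,-0.6477311021136137
G00114,1.1254286412572745
G00115,-0.21726317856237892
G00116,-0.1404226865712581
G00117,1.50304459050174
G00118,0.051480253269286014
G00119,-0.1801907851295923
G00120,-2.040807178147983
TF01,-2.11263826318805
TF02,-2.2527031781690177
TF03,-0.2168150045944231
TF04,-0.32958819620061797
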