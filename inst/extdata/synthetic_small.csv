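# stabmeta dataset schema v1
"publication_id","comparison_id","effect_id","crop","country","scale","response_measure","treatment_type","intensity","year","mean_t","disp_t","n_t","mean_c","disp_c","n_c","dispersion_kind","shared_control_id"
"pub001","pub001_c01","pub001_c01_e1","apple","synthetic","flower","measure_1","hand","high",1998,25.2296010384955,11.0497427043464,25,9.94692409893659,4.76455610472572,25,"SD","pub001_g01_m1"
"pub001","pub001_c01","pub001_c01_e2","apple","synthetic","flower","measure_2","hand","high",1998,24.3345635847585,12.0752404871499,25,8.80607697641246,3.71915058875648,25,"SD","pub001_g01_m2"
"pub001","pub001_c02","pub001_c02_e1","apple","synthetic","flower","measure_1","honeybee","low",1998,24.8776249562204,9.10930136365171,25,9.94692409893659,4.76455610472572,25,"SD","pub001_g01_m1"
"pub001","pub001_c02","pub001_c02_e2","apple","synthetic","flower","measure_2","honeybee","low",1998,22.0838781096883,8.57002199516763,25,8.80607697641246,3.71915058875648,25,"SD","pub001_g01_m2"
"pub001","pub001_c03","pub001_c03_e1","apple","synthetic","flower","measure_1","bumblebee","high",1998,16.2700026522608,4.34395723444923,11,10.0241465555637,3.11810356751776,11,"SD","pub001_g02_m1"
"pub001","pub001_c03","pub001_c03_e2","apple","synthetic","flower","measure_2","bumblebee","high",1998,15.1721896515514,2.74270076858789,11,9.6198309511266,4.90085832154382,11,"SD","pub001_g02_m2"
"pub002","pub002_c01","pub002_c01_e1","oilseed_rape","synthetic","plant","measure_1","honeybee","none",2011,35.5340809658973,14.1106679116219,17,13.2171208993809,7.7496688976292,17,"SD","pub002_g01_m1"
"pub002","pub002_c01","pub002_c01_e2","oilseed_rape","synthetic","plant","measure_2","honeybee","none",2011,38.0959184781207,24.4036275893414,17,10.0832058571067,4.05892616155725,17,"SD","pub002_g01_m2"
"pub002","pub002_c02","pub002_c02_e1","oilseed_rape","synthetic","plant","measure_1","bumblebee","none",2011,28.2861232141245,14.1100933211439,17,13.2171208993809,7.7496688976292,17,"SD","pub002_g01_m1"
"pub002","pub002_c02","pub002_c02_e2","oilseed_rape","synthetic","plant","measure_2","bumblebee","none",2011,28.9991950285587,11.6913527785107,17,10.0832058571067,4.05892616155725,17,"SD","pub002_g01_m2"
"pub002","pub002_c03","pub002_c03_e1","oilseed_rape","synthetic","plant","measure_1","hoverfly","none",2011,23.1196148520895,9.25184184830588,16,8.32802842415388,3.19554960641224,16,"SD","pub002_g02_m1"
"pub002","pub002_c03","pub002_c03_e2","oilseed_rape","synthetic","plant","measure_2","hoverfly","none",2011,20.5929235821225,8.82476436844954,16,8.48677122951919,3.56827695882868,16,"SD","pub002_g02_m2"
"pub003","pub003_c01","pub003_c01_e1","faba_bean","synthetic","plot_or_cohort","measure_1","bumblebee","none",1989,25.2091909631451,8.78001263817413,22,10.9875304849106,5.86073293768173,22,"SD","pub003_g01_m1"
"pub003","pub003_c01","pub003_c01_e2","faba_bean","synthetic","plot_or_cohort","measure_2","bumblebee","none",1989,23.036658939568,12.1835429129229,22,9.58810164967711,5.62771462372083,22,"SD","pub003_g01_m2"
"pub003","pub003_c02","pub003_c02_e1","faba_bean","synthetic","plot_or_cohort","measure_1","hoverfly","none",1989,21.118497854329,6.65813604903491,22,10.9875304849106,5.86073293768173,22,"SD","pub003_g01_m1"
"pub003","pub003_c02","pub003_c02_e2","faba_bean","synthetic","plot_or_cohort","measure_2","hoverfly","none",1989,22.8935578991175,9.35492241537663,22,9.58810164967711,5.62771462372083,22,"SD","pub003_g01_m2"
"pub003","pub003_c03","pub003_c03_e1","faba_bean","synthetic","plot_or_cohort","measure_1","solitary","none",1989,21.0100486170998,10.7042852406859,21,10.9167033980436,5.50274515168467,21,"SD","pub003_g02_m1"
"pub003","pub003_c03","pub003_c03_e2","faba_bean","synthetic","plot_or_cohort","measure_2","solitary","none",1989,24.3443761264718,7.55707336234116,21,9.83965804858361,4.52295572386522,21,"SD","pub003_g02_m2"
"pub004","pub004_c01","pub004_c01_e1","apple","synthetic","site","measure_1","hoverfly","none",2002,16.7582591225004,4.1190730543339,29,8.25944612655845,3.58618084369018,29,"SD","pub004_g01_m1"
"pub004","pub004_c01","pub004_c01_e2","apple","synthetic","site","measure_2","hoverfly","none",2002,17.9145448376125,4.39936309554601,29,9.13776564769008,3.22282914330779,29,"SD","pub004_g01_m2"
"pub004","pub004_c02","pub004_c02_e1","apple","synthetic","site","measure_1","solitary","none",2002,21.7791542240145,4.15674091445948,29,8.25944612655845,3.58618084369018,29,"SD","pub004_g01_m1"
"pub004","pub004_c02","pub004_c02_e2","apple","synthetic","site","measure_2","solitary","none",2002,17.9224971227751,2.73740856003777,29,9.13776564769008,3.22282914330779,29,"SD","pub004_g01_m2"
"pub004","pub004_c03","pub004_c03_e1","apple","synthetic","site","measure_1","open","none",2002,17.8288729155111,5.21650862427676,25,9.50730144715138,4.17540787459098,25,"SD","pub004_g02_m1"
"pub004","pub004_c03","pub004_c03_e2","apple","synthetic","site","measure_2","open","none",2002,20.1134589525561,5.45979704409075,25,10.5212336983587,5.97489269917461,25,"SD","pub004_g02_m2"
"pub005","pub005_c01","pub005_c01_e1","oilseed_rape","synthetic","flower","measure_1","solitary","none",2015,20.9164304709666,6.10915741040364,30,10.9817809163817,6.2262482075903,30,"SD","pub005_g01_m1"
"pub005","pub005_c01","pub005_c01_e2","oilseed_rape","synthetic","flower","measure_2","solitary","none",2015,26.5190335641525,6.66159326109022,30,11.7356214137697,6.04635993146305,30,"SD","pub005_g01_m2"
"pub005","pub005_c02","pub005_c02_e1","oilseed_rape","synthetic","flower","measure_1","open","none",2015,24.9927862445138,8.515710987145,30,10.9817809163817,6.2262482075903,30,"SD","pub005_g01_m1"
"pub005","pub005_c02","pub005_c02_e2","oilseed_rape","synthetic","flower","measure_2","open","none",2015,32.1522363100722,10.5803625308295,30,11.7356214137697,6.04635993146305,30,"SD","pub005_g01_m2"
"pub005","pub005_c03","pub005_c03_e1","oilseed_rape","synthetic","flower","measure_1","hand","none",2015,17.9471976967398,4.72382598795457,10,9.38219906895837,4.79801183131102,10,"SD","pub005_g02_m1"
"pub005","pub005_c03","pub005_c03_e2","oilseed_rape","synthetic","flower","measure_2","hand","none",2015,21.3921746952474,5.47182310914839,10,7.1463460587595,2.44570386716646,10,"SD","pub005_g02_m2"
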