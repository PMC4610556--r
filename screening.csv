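"feature","ks_statistic","ks_quantile","normal","log_transformed","r","statistic","quantile","retained","degenerate"
"bf",0.109572585400871,0.143356587260967,TRUE,FALSE,0.941522132006867,26.2122880167324,1.98728986483117,TRUE,FALSE
"ecd",0.120036139871498,0.143356587260967,TRUE,FALSE,0.929340700343991,23.6116950832634,1.98728986483117,TRUE,FALSE
"meol",0.0638701539339241,0.143356587260967,TRUE,FALSE,-0.843167594868262,-14.711431320997,1.98728986483117,TRUE,FALSE
"yf",0.0768518711298229,0.143356587260967,TRUE,FALSE,0.913069122229439,21.0035463188068,1.98728986483117,TRUE,FALSE
"pns",0.0685501996726598,0.143356587260967,TRUE,FALSE,0.891390467916845,18.4495064388608,1.98728986483117,TRUE,FALSE
"sdsa",0.0653959614249152,0.143356587260967,TRUE,FALSE,-0.829570846882351,-13.9363247818477,1.98728986483117,TRUE,FALSE
"fald",0.0715106129393999,0.143356587260967,TRUE,FALSE,0.866615784448733,16.2925193158499,1.98728986483117,TRUE,FALSE
"sdvs",0.0902739597299302,0.143356587260967,TRUE,FALSE,0.905404971072593,20.0058222846775,1.98728986483117,TRUE,FALSE
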