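sample_id,group,run,protein,peptide,intensity_endogenous,intensity_reference
S0001,1,R0001,PROT1,pep01,5509.4983036646936,27250.08455319214
S0001,1,R0001,PROT1,pep02,9451.5330102661865,20458.501276588297
S0001,1,R0001,PROT1,pep03,8358.6826212950928,50914.178157779068
S0002,2,R0002,PROT1,pep01,14911.255535232322,12462.026490641672
S0002,2,R0002,PROT1,pep02,6372.3532591371186,16285.944870668154
S0002,2,R0002,PROT1,pep03,11450.4135118414,8512.9127228623347
S0003,1,R0003,PROT1,pep01,14035.975890178543,18388.76052240959
S0003,1,R0003,PROT1,pep02,21878.755290981549,25173.393552930393
S0003,1,R0003,PROT1,pep03,57053.149681633047,70381.544453130206
S0004,2,R0004,PROT1,pep01,16097.528483050897,26048.272677587578
S0004,2,R0004,PROT1,pep02,10049.859964836713,31454.265069341654
S0004,2,R0004,PROT1,pep03,9273.806348748798,17649.016547845342
S0005,1,R0005,PROT1,pep01,18896.495276432153,13743.941129947185
S0005,1,R0005,PROT1,pep02,66236.850046938518,37914.344843443512
S0005,1,R0005,PROT1,pep03,23247.669565072971,43107.830800469361
S0006,2,R0006,PROT1,pep01,13114.664825422524,20225.741193856895
S0006,2,R0006,PROT1,pep02,33687.682207168873,21194.08406235107
S0006,2,R0006,PROT1,pep03,41621.104175342487,42642.203693389121
S0007,1,R0007,PROT1,pep01,30011.766131826305,30791.164126485386
S0007,1,R0007,PROT1,pep02,24535.102190249498,13360.310548274258
S0007,1,R0007,PROT1,pep03,69663.322684934377,46334.876030940577
S0008,2,R0008,PROT1,pep01,36487.256648505601,22870.128765008034
S0008,2,R0008,PROT1,pep02,32190.412310451775,32178.841454745012
S0008,2,R0008,PROT1,pep03,67524.63826059665,38241.844064875899
S0009,1,R0009,PROT1,pep01,36722.571909640465,51567.880325035345
S0009,1,R0009,PROT1,pep02,86333.141328522252,32676.367468255128
S0009,1,R0009,PROT1,pep03,126344.97925390425,45733.200081587711
S0010,2,R0010,PROT1,pep01,48438.726067335505,51645.139671345176
S0010,2,R0010,PROT1,pep02,50928.254700216319,90254.65526442774
S0010,2,R0010,PROT1,pep03,95599.341664954874,25237.298093305799
S0011,1,R0011,PROT1,pep01,92012.379004936127,46121.531532841771
S0011,1,R0011,PROT1,pep02,44674.144675567608,156759.30437306414
S0011,1,R0011,PROT1,pep03,166358.36290712291,56730.520464382505
S0012,2,R0012,PROT1,pep01,49443.298565928584,57377.206853995704
S0012,2,R0012,PROT1,pep02,206603.25107162868,95960.162086427517
S0012,2,R0012,PROT1,pep03,64506.681707654025,50247.512043030285
S0001,1,R0001,PROT2,pep01,6697.7894417471034,19313.887682396773
S0001,1,R0001,PROT2,pep02,11632.890837908084,12755.063733485111
S0001,1,R0001,PROT2,pep03,10786.706165801508,45782.851715594741
S0002,2,R0002,PROT2,pep01,19123.125496581353,21005.413341875887
S0002,2,R0002,PROT2,pep02,42688.016047976256,35156.486887825886
S0002,2,R0002,PROT2,pep03,11109.402241788568,19260.990028972999
S0003,1,R0003,PROT2,pep01,10597.825777122292,9411.0262237748211
S0003,1,R0003,PROT2,pep02,8406.7149776614515,26496.593626227859
S0003,1,R0003,PROT2,pep03,35552.374103716284,35879.515882344451
S0004,2,R0004,PROT2,pep01,17021.065020464925,54462.237122762039
S0004,2,R0004,PROT2,pep02,13278.177298818542,29209.48870679559
S0004,2,R0004,PROT2,pep03,27219.285435055735,17487.781724896424
S0005,1,R0005,PROT2,pep01,11864.515015606659,35596.712433268171
S0005,1,R0005,PROT2,pep02,10626.3126876071,53322.592121710615
S0005,1,R0005,PROT2,pep03,31504.501531091504,49413.242151707622
S0006,2,R0006,PROT2,pep01,40438.806372023733,25399.607326910929
S0006,2,R0006,PROT2,pep02,54200.936150967733,34175.874245922394
S0006,2,R0006,PROT2,pep03,33130.308978885783,51171.268959550136
S0007,1,R0007,PROT2,pep01,26784.915040420532,30100.732729953976
S0007,1,R0007,PROT2,pep02,32271.060569361762,44598.568869905248
S0007,1,R0007,PROT2,pep03,38416.098462194204,28628.59912987662
S0008,2,R0008,PROT2,pep01,101958.36175603778,27215.794951205204
S0008,2,R0008,PROT2,pep02,70957.49866117067,31701.699427702115
S0008,2,R0008,PROT2,pep03,68077.799997583599,66907.225635499868
S0009,1,R0009,PROT2,pep01,16588.12762429658,28650.792845064112
S0009,1,R0009,PROT2,pep02,50843.020545997388,22839.202608373591
S0009,1,R0009,PROT2,pep03,43802.069635458356,75021.122119482039
S0010,2,R0010,PROT2,pep01,129408.13766671572,210606.80624927281
S0010,2,R0010,PROT2,pep02,81058.668679834751,27921.680157197625
S0010,2,R0010,PROT2,pep03,21290.863248907601,167248.7393951402
S0011,1,R0011,PROT2,pep01,18838.440069650369,26976.115158587832
S0011,1,R0011,PROT2,pep02,91754.709550193351,58996.395333805063
S0011,1,R0011,PROT2,pep03,113326.915753351,170013.27040551149
S0012,2,R0012,PROT2,pep01,67176.485381457387,34230.89182627359
S0012,2,R0012,PROT2,pep02,177110.56798403343,47185.607259987686
S0012,2,R0012,PROT2,pep03,146326.86476608427,96112.795348540662
S0001,1,R0001,PROT3,pep01,12705.266516586658,5203.3664044421248
S0001,1,R0001,PROT3,pep02,4535.0591124557122,40683.40523776292
S0001,1,R0001,PROT3,pep03,24734.337347197175,52186.688998717902
S0002,2,R0002,PROT3,pep01,4948.6745374172015,31758.700506190071
S0002,2,R0002,PROT3,pep02,16418.988923623587,17845.720886507163
S0002,2,R0002,PROT3,pep03,7426.2062268353893,20861.535310800846
S0003,1,R0003,PROT3,pep01,12108.987268084213,13154.798584497499
S0003,1,R0003,PROT3,pep02,18147.959872990963,14270.580960948906
S0003,1,R0003,PROT3,pep03,12938.672930828772,8957.093327776005
S0004,2,R0004,PROT3,pep01,23144.897917341867,53261.349365770242
S0004,2,R0004,PROT3,pep02,22681.707268151189,32072.890893445645
S0004,2,R0004,PROT3,pep03,17523.600308860761,46253.984976803229
S0005,1,R0005,PROT3,pep01,17594.254784519311,18599.701280436955
S0005,1,R0005,PROT3,pep02,27800.100159245972,25637.687531122894
S0005,1,R0005,PROT3,pep03,38692.820653652903,63232.197120694247
S0006,2,R0006,PROT3,pep01,31324.469223224438,32828.318284091874
S0006,2,R0006,PROT3,pep02,23296.756444067199,32512.585517614811
S0006,2,R0006,PROT3,pep03,44047.055181181095,16973.82998683551
S0007,1,R0007,PROT3,pep01,35589.739195605791,17405.169383512268
S0007,1,R0007,PROT3,pep02,68374.783651604535,10183.448770301531
S0007,1,R0007,PROT3,pep03,106264.99280295045,46762.97163942513
S0008,2,R0008,PROT3,pep01,28687.832571016552,25928.584321808834
S0008,2,R0008,PROT3,pep02,27435.069384492796,24184.499926472618
S0008,2,R0008,PROT3,pep03,56750.427964552589,80052.423737219098
S0009,1,R0009,PROT3,pep01,23292.80177865873,18276.741613622289
S0009,1,R0009,PROT3,pep02,140215.77550437936,57400.61530546446
S0009,1,R0009,PROT3,pep03,142306.81741721072,47298.155687175458
S0010,2,R0010,PROT3,pep01,32714.736283752984,54013.972692853044
S0010,2,R0010,PROT3,pep02,80054.786976079398,32534.740376008143
S0010,2,R0010,PROT3,pep03,67229.390408128151,47359.116367959126
S0011,1,R0011,PROT3,pep01,25470.271253988198,40172.558401950344
S0011,1,R0011,PROT3,pep02,104957.8230645291,83265.940226808831
S0011,1,R0011,PROT3,pep03,193290.37831815114,57262.878461754626
S0012,2,R0012,PROT3,pep01,88899.51828312561,60321.585556589991
S0012,2,R0012,PROT3,pep02,153533.60654424451,103069.92440352798
S0012,2,R0012,PROT3,pep03,130883.60012119218,54462.496509545083
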