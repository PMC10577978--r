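metal,parameterization,contrast,cases_exposed,noncases_exposed,cases_ref,noncases_ref
iAs,percentile,p50_90,43709,487868,55433,609926
iAs,percentile,p90,10757,121378,55433,609926
iAs,exceedance,ge25pct,1900,107999,21286,1197886
Cd,percentile,p50_90,43653,488279,55164,609466
Cd,percentile,p90,11082,121427,55164,609466
Cd,exceedance,ge25pct,466,109433,4819,1214353
Cr,percentile,p50_90,43538,488409,55735,608834
Cr,percentile,p90,10626,121929,55735,608834
Cr,exceedance,ge25pct,49,109850,435,1214353
Cu,percentile,p50_90,43089,488791,56031,608590
Cu,percentile,p90,10779,121791,56031,608590
Cu,exceedance,ge25pct,389,109510,4332,1214840
Pb,percentile,p50_90,43740,487904,54784,609888
Pb,percentile,p90,11375,121380,54784,609888
Pb,exceedance,ge25pct,2642,107257,27565,1191607
Mn,percentile,p50_90,43761,488057,55515,609411
Mn,percentile,p90,10623,121704,55515,609411
Mn,exceedance,ge25pct,3678,106221,42515,1176657
Zn,percentile,p50_90,43642,487844,55763,608922
Zn,percentile,p90,10494,122406,55763,608922
Zn,exceedance,ge25pct,699,109200,9055,1210117
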