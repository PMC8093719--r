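stratum,area,survey_years,sample_type,collected,scored,unique_genotypes
Flin Flon,Flin Flon,2014,fecal,336,320,104
La Ronge,La Ronge,2013+2015,fecal,497,403,162
SK Boreal Plains West,SK Boreal Plains West,2016,fecal,242,233,122
Patterson Lake,Patterson Lake,2018,fecal,21,19,9
SK2 Central,SK2 Central,2017,fecal,452,371,150
SK Shield 2014,SK Shield,2014,fecal,99,98,98
SK Shield 2019,SK Shield,2019,blood,551,526,288
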