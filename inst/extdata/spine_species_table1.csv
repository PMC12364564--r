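family,species,svl_mm,spine_count,spine_count_underestimated,largest_spine_volume_mm3,highest_structural_curvature_deg
Colubridae,Ahaetulla nasuta,628,489,FALSE,0.02372,45.79
Colubridae,Nerodia fasciata,516,955,FALSE,0.26906,97.69
Colubridae,Nerodia rhombifer,664,2698,TRUE,1.04361,54.58
Colubridae,Nerodia sipedon,487,1292,TRUE,0.24166,109.69
Colubridae,Opheodrys aestivus,na,769,FALSE,0.11474,73.68
Colubridae,Pantherophis alleghaniensis,1222,469,FALSE,0.03729,26.56
Colubridae,Pantherophis guttatus,805,337,FALSE,0.00629,36.7
Elapidae,Acanthophis rugosus,480,419,FALSE,0.00794,24.55
Lamprophiidae,Mehelya crossi,1055,975,FALSE,0.01896,76.01
Viperidae,Crotalus atrox,827,301,FALSE,0.03822,16.89
Viperidae,Crotalus viridis,763,308,FALSE,0.03822,28.89
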