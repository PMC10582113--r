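system,status,site,mean15N,mean13C,mean_TL,mean_W
Lake,native,Gala,15.8,-27.5,153.0,59.9
Lake,native,Sigirci,15.2,-23.6,172.6,111.8
Reservoir,translocated,Bayat,7.9,-28.5,158.0,44.8
Reservoir,translocated,Ozburun,13.2,-28.4,169.3,61.4
Reservoir,translocated,Seyitler,13.8,-21.9,229.3,174.2
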