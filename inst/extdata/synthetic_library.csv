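name,sequence,modified,planted_kind
SP01,KWFWVAALWVAF,TRUE,aggregator
SP02,RWAFLAVALAKL,TRUE,aggregator
SP03,KWYALAAVLKAA,TRUE,aggregator
SP04,KRWKAVLAVFAL,TRUE,transient
SP05,KKWHARVFAVLA,TRUE,transient
SP06,RKAWVALKVAFL,TRUE,transient
SP07,KHRWAVALVKFA,TRUE,transient
SP08,KKRKAKRVKALK,TRUE,non_aggregator
SP09,RKKRAKVKLKAK,TRUE,non_aggregator
SP10,KRKKHAKVKKAL,TRUE,non_aggregator
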