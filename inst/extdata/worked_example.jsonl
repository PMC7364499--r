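{"doc_id":"worked-example","sentences":[["The","deletion","mutation","on","exon","19","of","the","EGFR","gene","was","present","in","16","patients","while","The","L858E","point","mutation","on","exon","21","was","noted","in","10"],["All","patients","were","treated","with","gefitinib","and","showed","a","partial","response"]],"mentions":[{"role":"drug","entity_id":"gefitinib","sentence_index":1,"token_start":5,"token_end":6},{"role":"gene","entity_id":"EGFR","sentence_index":0,"token_start":8,"token_end":9},{"role":"mutation","entity_id":"L858E","sentence_index":0,"token_start":17,"token_end":18}],"label":"response"}
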