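study,language,gender,f1a,f1i,f2i,f2u
hillenbrand1995,english,male,768,342,2322,997
hillenbrand1995,english,female,936,437,2761,1105
kiel_read_speech,german,male,784,292,2181,721
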