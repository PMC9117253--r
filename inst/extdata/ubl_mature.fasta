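>Ub|P0CG48 ubiquitin, mature monomer (76 aa)
MQIFVKTLTGKTITLEVEPSDTIENVKAKIQDKEGIPPDQQRLIFAGKQLEDGRTLSDYN
IQKESTLHLVLRLRGG
>NEDD8|Q15843 NEDD8, mature (1-76, truncated at C-terminal diGly)
MLIKVKTLTGKEIEIDIEPTDKVERIKERVEEKEGIPPQQQRLIYSGKQMNDEKTAADYK
ILGGSVLHLVLALRGG
>SUMO1|P63165 SUMO1, mature (1-97, truncated at C-terminal diGly)
MSDQEAKPSTEDLGDKKEGEYIKLKVIGQDSSEIHFKVKMTTHLKKLKESYCQRQGVPMN
SLRFLFEGQRIADNHTPKELGMEEEDVIEVYQEQTGG
>SUMO2|P61956 SUMO2, mature (1-93, truncated at C-terminal diGly)
MADEKPKEGVKTENNDHINLKVAGQDGSVVQFKIKRHTPLSKLMKAYCERQGLSMRQIRF
RFDGQPINETDTPAQLEMEDEDTIDVFQQQTGG
>SUMO3|P55854 SUMO3, mature (1-92, truncated at C-terminal diGly)
MSEEKPKEGVKTENDHINLKVAGQDGSVVQFKIKRHTPLSKLMKAYCERQGLSMRQIRFR
FDGQPINETDTPAQLEMEDEDTIDVFQQQTGG
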