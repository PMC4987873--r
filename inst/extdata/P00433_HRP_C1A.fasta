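>P00433 Peroxidase C1A precursor (horseradish), bundled reference sequence
MHFSSSSTLFTCITLIPLVCLILHASLSDAQLTPTFYDNSCPNVSNIVRDTIVNELRSDP
RIAASILRLHFHDCFVNGCDASILLDNTTSFRTEKDAFGNANSARGFPVIDRMKAAVESA
CPRTVSCADLLTIAAQQSVTLAGGPSWRVPLGRRDSLQAFLDLANANLPAPFFTLPQLKD
SFRNVGLNRSSDLVALSGGHTFGKNQCRFIMDRLYNFSNTGLPDPTLNTTYLQTLRGLCP
LNGNLSALVDFDLRTPTIFDNKYYVNLEEQKGLIQSDQELFSSPNATDTIPLVRSFANST
QTFFNAFVEAMDRMGNITPLTGTQGQIRLNCRVVNSNSLLHDMVEVVDFVSSM
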