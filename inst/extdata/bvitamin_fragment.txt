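21 exp pyridoxine/
22 pyridoxal.ti.
23 (vitamin adj1 ("B6" or "B 6")).mp.
24 or/21-23
25 random:.sh,pt.
26 limit 25 to English language
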