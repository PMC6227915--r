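year,total_thousands
1950,2571129
2017,7640466
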