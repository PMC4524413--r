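mz
149.02332
391.28429
413.26623
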