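# Dutch speculation keywords, one per line.
mogelijk
mogelijke
waarschijnlijk
verdacht
verdenking
vermoedelijk
wellicht
misschien
dd
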