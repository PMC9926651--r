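predicted,intact,logged,burned
intact,1612,47,107
logged,194,366,26
burned,82,16,991
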