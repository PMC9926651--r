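site_id,dclass,mean,sd
feliz_natal+xingu,intact,89.2,10.2
feliz_natal+xingu,logged,93.9,16.3
feliz_natal+xingu,burned,57.9,35.0
saraca,intact,185.3,31.9
saraca,logged,156.8,26.0
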