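region,length_bp
18S,27
ITS1,238
5.8S,164
ITS2,213
26S,22
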