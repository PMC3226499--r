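chemical,vbs
5HPP-33,6.61
Thalidomide,1.76
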