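# Etiology annotation for a 30-signature COSMIC-v2-style reference.
# Edit freely; every signature column used in a fit must be mapped.
Signature.1: aging
Signature.2: APOBEC
Signature.3: other
Signature.4: other
Signature.5: other
Signature.6: MMR
Signature.7: UV
Signature.8: other
Signature.9: POLH
Signature.10: POLE
Signature.11: other
Signature.12: other
Signature.13: APOBEC
Signature.14: other
Signature.15: MMR
Signature.16: other
Signature.17: other
Signature.18: other
Signature.19: other
Signature.20: MMR
Signature.21: other
Signature.22: other
Signature.23: other
Signature.24: other
Signature.25: other
Signature.26: MMR
Signature.27: other
Signature.28: other
Signature.29: other
Signature.30: other
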