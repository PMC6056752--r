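>ETN_SYN synthetic Etanercept-like Fc-fusion (toy sequence)
LPAQVAFTPYAPEPGSTCRAAAKVFCTKSSSSPAGGTTDRVKGGPSVFGGKDTGGLSRTT
PEVTGVGGK
>ABT_SYN synthetic Abatacept-like Fc-fusion (toy sequence)
MHVAQPAVVLASSRGIASFVCEYASPGKATEVRVTVLRGGPSVFGGKDTGGLSRTTPEVT
GVGGK
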