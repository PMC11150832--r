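# MS2 spectrum of the protonated tetraether cardiolipin with 64 alkyl
# carbons (C33 DEG / C31 DEG cores), as observed by UHPLC-HRMSn.
BEGIN IONS
TITLE=tetraether-CDL-64
PEPMASS=1298.0630
RTINSECONDS=1185.00
CHARGE=1+
155.0100 65.0000
234.9770 60.0000
255.2680 80.0000
283.2990 75.0000
297.3150 70.0000
663.5310 55.0000
691.5630 58.0000
743.4970 85.0000
771.5290 90.0000
1280.0500 100.0000
END IONS
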