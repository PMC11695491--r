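BEGIN IONS
TITLE=F01
PEPMASS=140.07058
RTINSECONDS=582.6
65.0386 12000
94.0651 43000
122.0600 81000
END IONS

BEGIN IONS
TITLE=F02
PEPMASS=187.06011
RTINSECONDS=636.6
85.0283 95000
99.0440 64000
127.0389 72000
169.0495 21000
END IONS

BEGIN IONS
TITLE=F03
PEPMASS=215.05504
RTINSECONDS=636.6
85.0283 88000
99.0440 59000
127.0389 69000
197.0444 18000
END IONS

BEGIN IONS
TITLE=F04
PEPMASS=247.08126
RTINSECONDS=636.6
85.0283 91000
99.0440 61000
127.0389 67000
229.0707 15000
END IONS

BEGIN IONS
TITLE=F05
PEPMASS=233.06561
RTINSECONDS=636.6
85.0283 86000
99.0440 57000
127.0389 64000
215.0550 13000
END IONS

BEGIN IONS
TITLE=F06
PEPMASS=201.03933
RTINSECONDS=636.6
85.0283 84000
99.0440 55000
127.0389 62000
183.0288 11000
END IONS

BEGIN IONS
TITLE=F07
PEPMASS=264.10776
RTINSECONDS=648.6
84.0444 34000
130.0499 52000
218.1023 19000
END IONS

BEGIN IONS
TITLE=F08
PEPMASS=281.05753
RTINSECONDS=874.8
139.0189 27000
167.0495 45000
245.0808 16000
END IONS

BEGIN IONS
TITLE=F09
PEPMASS=247.09648
RTINSECONDS=900.6
107.0491 38000
135.0441 56000
229.0859 22000
END IONS

BEGIN IONS
TITLE=F10
PEPMASS=211.06016
RTINSECONDS=913.8
95.0491 31000
123.0441 49000
193.0495 17000
END IONS

BEGIN IONS
TITLE=F11
PEPMASS=151.03905
RTINSECONDS=913.8
65.0386 29000
93.0335 47000
123.0441 36000
END IONS

BEGIN IONS
TITLE=F12
PEPMASS=406.18602
RTINSECONDS=923.4
91.0542 26000
159.0441 33000
187.0753 58000
388.1755 14000
END IONS

BEGIN IONS
TITLE=F13
PEPMASS=187.07534
RTINSECONDS=923.4
115.0542 41000
141.0699 63000
169.0648 37000
END IONS
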