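NAME: atenolol
PRECURSORMZ: 267.17087
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C14H22N2O3
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 6
178.08630	60.000
190.08630	68.000
208.09680	76.000
225.12340	84.000
249.15970	92.000
250.14380	100.000

NAME: atenolol
PRECURSORMZ: 267.17087
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C14H22N2O3
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 11
72.08080	30.000
74.06000	35.000
98.09640	40.000
116.10700	45.000
134.06000	50.000
178.08630	55.000
190.08630	60.000
208.09680	65.000
225.12340	70.000
249.15970	75.000
250.14380	80.000

NAME: atenolol
PRECURSORMZ: 267.17087
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C14H22N2O3
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: enrofloxacin
PRECURSORMZ: 360.17234
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C19H22FN3O3
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 2
316.18200	60.000
342.16120	100.000

NAME: enrofloxacin
PRECURSORMZ: 360.17234
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C19H22FN3O3
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 4
231.09280	30.000
245.10850	46.667
316.18200	63.333
342.16120	80.000

NAME: enrofloxacin
PRECURSORMZ: 360.17234
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C19H22FN3O3
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: erythromycin
PRECURSORMZ: 734.46906
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C37H67NO13
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 3
558.36360	60.000
576.37420	80.000
716.45790	100.000

NAME: erythromycin
PRECURSORMZ: 734.46906
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C37H67NO13
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 5
158.11760	30.000
540.35310	42.500
558.36360	55.000
576.37420	67.500
716.45790	80.000

NAME: erythromycin
PRECURSORMZ: 734.46906
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C37H67NO13
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: ketoprofen
PRECURSORMZ: 255.10212
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 1
209.09610	100.000

NAME: ketoprofen
PRECURSORMZ: 255.10212
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 2
105.03350	30.000
209.09610	80.000

NAME: ketoprofen
PRECURSORMZ: 255.10212
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: sulfamethoxazole
PRECURSORMZ: 254.05994
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 2
108.04439	60.000
156.01140	100.000

NAME: sulfamethoxazole
PRECURSORMZ: 254.05994
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 3
92.04950	30.000
108.04439	55.000
156.01140	80.000

NAME: sulfamethoxazole
PRECURSORMZ: 254.05994
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: tetracycline
PRECURSORMZ: 445.16109
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 1
428.13400	100.000

NAME: tetracycline
PRECURSORMZ: 445.16109
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 2
410.12340	30.000
428.13400	80.000

NAME: tetracycline
PRECURSORMZ: 445.16109
PRECURSORTYPE: [M+H]+
IONMODE: Positive
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

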