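NAME: ketoprofen
PRECURSORMZ: 253.08647
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 1
209.09720	100.000

NAME: ketoprofen
PRECURSORMZ: 253.08647
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 1
209.09720	80.000

NAME: ketoprofen
PRECURSORMZ: 253.08647
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C16H14O3
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: sulfamethoxazole
PRECURSORMZ: 252.04429
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 1
156.01250	100.000

NAME: sulfamethoxazole
PRECURSORMZ: 252.04429
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 2
92.05060	30.000
156.01250	80.000

NAME: sulfamethoxazole
PRECURSORMZ: 252.04429
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C10H11N3O3S
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

NAME: tetracycline
PRECURSORMZ: 443.14544
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=10; synthetic CE split
Num Peaks: 2
273.07680	60.000
426.11940	100.000

NAME: tetracycline
PRECURSORMZ: 443.14544
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=20; synthetic CE split
Num Peaks: 3
271.06120	30.000
273.07680	55.000
426.11940	80.000

NAME: tetracycline
PRECURSORMZ: 443.14544
PRECURSORTYPE: [M-H]-
IONMODE: Negative
FORMULA: C22H24N2O8
COMMENT: Tentative=false; CE=40; synthetic CE split
Num Peaks: 2
53.03860	100.000
65.03860	70.000

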