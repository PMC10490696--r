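year,DRA,PAF,WOL,GRL,UNL,COL,NAW,REP
1990,284.32,34.10,519.40,259.02,79.52,26.20,79.27,3.38
1995,317.91,38.81,504.09,240.28,70.01,29.73,72.13,3.37
2000,323.84,45.00,499.36,234.54,69.88,29.15,68.72,3.81
2005,325.65,44.90,499.26,234.05,68.98,29.57,67.03,3.83
2010,319.48,52.54,504.56,188.01,104.74,33.87,98.78,4.02
2015,317.36,55.48,504.43,186.64,104.41,34.57,98.40,4.06
2020,321.01,64.95,498.93,169.99,113.37,37.46,104.79,5.30
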