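"specimen_id","year","station","sl_mm","d15n_glu","d15n_ala","d15n_pro","d15n_phe","d15n_gly","d15n_bulk"
"1994_01",1994,NA,19.9,23.2,23.82,23.63,7.67,8.04,NA
"1994_02",1994,NA,22.4,22.44,22.58,22.56,8.18,7.85,NA
"1994_03",1994,NA,20.2,20.02,20.24,20.21,8.08,8.13,NA
"1995_01",1995,NA,22.8,21.71,21.35,21.07,7.87,7.93,NA
"1995_02",1995,NA,18.6,26.37,26.34,26.21,8.04,8.15,NA
"1995_03",1995,NA,22.9,23.44,23.84,23.95,7.95,8.22,NA
"1996_01",1996,NA,19.4,21.98,21.77,21.48,7.62,7.57,NA
"1996_02",1996,NA,20.5,23.74,24.16,24.26,7.81,7.32,NA
"1996_03",1996,NA,21.2,21.9,22.08,21.84,7.79,7.83,NA
"1996_04",1996,NA,22.6,22.45,22.26,22.58,7.87,7.74,NA
"1997_01",1997,NA,19.3,21.74,21.58,21.55,7.78,7.69,NA
"1997_02",1997,NA,22.2,23.88,23.66,23.43,7.7,7.56,NA
"1997_03",1997,NA,18.7,20.9,21.34,21.51,7.88,7.74,NA
"1998_01",1998,NA,22.9,22.36,22.52,22.22,7.7,7.86,NA
"1998_02",1998,NA,22.1,21.25,21.18,20.93,7.54,8.07,NA
"1998_03",1998,NA,21,21.82,22.21,21.79,7.61,7.43,NA
"1998_04",1998,NA,20.6,21.34,21.01,21.02,7.6,8,NA
"1999_01",1999,NA,18.5,21.83,21.91,21.81,7.65,7.66,NA
"1999_02",1999,NA,18.4,20.33,20.13,20.06,7.71,7.62,NA
"1999_03",1999,NA,22.4,21.92,21.91,21.66,7.64,7.75,NA
"2000_01",2000,NA,21.7,19,18.94,19.21,7.06,7.39,NA
"2000_02",2000,NA,20.1,21.14,21.09,21.33,7.12,7.17,NA
"2000_03",2000,NA,21.5,21.79,21.96,22.13,7.06,7.15,NA
"2001_01",2001,NA,21.5,21.88,22.12,22.09,7.52,7.09,NA
"2001_02",2001,NA,21.2,22,22.22,21.88,7.36,7.19,NA
"2001_03",2001,NA,19.1,20.47,20.47,20.41,7.35,7.59,NA
"2001_04",2001,NA,19.1,21.44,20.95,21.27,7.2,7.36,NA
"2002_01",2002,NA,19,20.99,21.24,21.17,7.43,7.45,NA
"2002_02",2002,NA,19.5,16.39,16.75,16.31,7.57,7.42,NA
"2002_03",2002,NA,21.2,20.7,20.67,20.69,7.42,7.35,NA
"2002_04",2002,NA,19.1,21.53,21.32,21.23,7.41,7.37,NA
"2003_01",2003,NA,21.5,16.95,16.7,16.24,7.66,7.63,NA
"2003_02",2003,NA,21.8,19.74,20.17,20.4,7.54,7.43,NA
"2003_03",2003,NA,18.9,20.98,20.99,21.03,7.59,7.75,NA
"2003_04",2003,NA,19.7,19.71,20.02,19.89,7.55,7.78,NA
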