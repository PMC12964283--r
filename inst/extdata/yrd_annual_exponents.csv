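year,scale_index,goodness_of_fit,classification
2000,0.7773,0.6847,Negative allometric level 1
2001,0.7913,0.7061,Negative allometric level 1
2002,0.8244,0.7164,Negative allometric level 1
2003,0.8395,0.7436,Negative allometric level 1
2004,0.8501,0.7455,Positive allometric level 1
2005,0.8622,0.7483,Positive allometric level 1
2006,0.8742,0.7655,Positive allometric level 1
2007,0.9004,0.7996,Positive allometric level 1
2008,0.9054,0.8339,Positive allometric level 1
2009,0.9358,0.8634,Positive allometric level 1
2010,0.9395,0.9011,Positive allometric level 1
2011,0.9512,0.9107,Positive allometric level 1
2012,0.9662,0.9334,Positive allometric level 1
2013,0.9747,0.9379,Positive allometric level 1
2014,0.9649,0.9324,Positive allometric level 1
2015,1.0527,0.9458,Positive allometric level 2
2016,1.0524,0.9456,Positive allometric level 2
2017,1.0604,0.9010,Positive allometric level 2
2018,1.0572,0.9026,Positive allometric level 2
2019,1.0541,0.9082,Positive allometric level 2
2020,1.0410,0.9432,Positive allometric level 2
2021,1.0453,0.9406,Positive allometric level 2
2022,1.0319,0.9483,Positive allometric level 2
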