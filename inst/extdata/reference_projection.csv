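"year","cohort_size","state","count","share_printed"
2016,5449204,"NORMO",4026612,"74"
2016,5449204,"MICRO",578720,"10.6"
2016,5449204,"MACRO",118084,"2.2"
2016,5449204,"ESRD",28750,"0.53"
2016,5449204,"DEATH_CV",697039,"12.8"
2017,5703343,"NORMO",4124684,"72.3"
2017,5703343,"MICRO",626333,"11.0"
2017,5703343,"MACRO",133416,"2.3"
2017,5703343,"ESRD",31562,"0.55"
2017,5703343,"DEATH_CV",787347,"13.8"
2018,5963455,"NORMO",4225015,"70.8"
2018,5963455,"MICRO",672847,"11.3"
2018,5963455,"MACRO",149127,"2.5"
2018,5963455,"ESRD",34415,"0.58"
2018,5963455,"DEATH_CV",882051,"14.8"
2019,6229519,"NORMO",4327494,"69.5"
2019,6229519,"MICRO",718388,"11.5"
2019,6229519,"MACRO",165159,"2.7"
2019,6229519,"ESRD",37307,"0.60"
2019,6229519,"DEATH_CV",981171,"15.8"
2020,6501512,"NORMO",4432015,"68.2"
2020,6501512,"MICRO",763074,"11.7"
2020,6501512,"MACRO",181460,"2.8"
2020,6501512,"ESRD",40236,"0.62"
2020,6501512,"DEATH_CV",1084727,"16.7"
2021,6779409,"NORMO",4538472,"66.9"
2021,6779409,"MICRO",807011,"11.9"
2021,6779409,"MACRO",197987,"2.9"
2021,6779409,"ESRD",43199,"0.64"
2021,6779409,"DEATH_CV",1192739,"17.6"
2022,7063191,"NORMO",4646773,"65.8"
2022,7063191,"MICRO",850296,"12.0"
2022,7063191,"MACRO",214704,"3.0"
2022,7063191,"ESRD",46194,"0.65"
2022,7063191,"DEATH_CV",1305225,"18.5"
2023,7352844,"NORMO",4756831,"64.7"
2023,7352844,"MICRO",893015,"12.1"
2023,7352844,"MACRO",231581,"3.1"
2023,7352844,"ESRD",49216,"0.67"
2023,7352844,"DEATH_CV",1422201,"19.3"
2024,7648353,"NORMO",4868561,"63.7"
2024,7648353,"MICRO",935250,"12.2"
2024,7648353,"MACRO",248592,"3.3"
2024,7648353,"ESRD",52264,"0.68"
2024,7648353,"DEATH_CV",1543686,"20.2"
2025,7949693,"NORMO",4981876,"62.7"
2025,7949693,"MICRO",977072,"12.29"
2025,7949693,"MACRO",265716,"3.34"
2025,7949693,"ESRD",55335,"0.70"
2025,7949693,"DEATH_CV",1669695,"21.00"
2026,8256841,"NORMO",5096690,"61.7"
2026,8256841,"MICRO",1018546,"12.34"
2026,8256841,"MACRO",282938,"3.43"
2026,8256841,"ESRD",58425,"0.71"
2026,8256841,"DEATH_CV",1800243,"21.80"
2027,8569754,"NORMO",5212900,"60.8"
2027,8569754,"MICRO",1059731,"12.37"
2027,8569754,"MACRO",300243,"3.50"
2027,8569754,"ESRD",61533,"0.72"
2027,8569754,"DEATH_CV",1935346,"22.58"
2028,8888350,"NORMO",5330372,"60.0"
2028,8888350,"MICRO",1100681,"12.38"
2028,8888350,"MACRO",317622,"3.57"
2028,8888350,"ESRD",64657,"0.73"
2028,8888350,"DEATH_CV",2075018,"23.35"
2029,9212529,"NORMO",5448955,"59.1"
2029,9212529,"MICRO",1141441,"12.39"
2029,9212529,"MACRO",335065,"3.64"
2029,9212529,"ESRD",67795,"0.74"
2029,9212529,"DEATH_CV",2219273,"24.09"
2030,9542175,"NORMO",5568490,"58.4"
2030,9542175,"MICRO",1182050,"12.39"
2030,9542175,"MACRO",352566,"3.69"
2030,9542175,"ESRD",70945,"0.74"
2030,9542175,"DEATH_CV",2368122,"24.82"
2031,9877143,"NORMO",5688796,"57.6"
2031,9877143,"MICRO",1222543,"12.38"
2031,9877143,"MACRO",370121,"3.75"
2031,9877143,"ESRD",74108,"0.75"
2031,9877143,"DEATH_CV",2521576,"25.53"
2032,10217299,"NORMO",5809707,"56.9"
2032,10217299,"MICRO",1262945,"12.40"
2032,10217299,"MACRO",387724,"3.79"
2032,10217299,"ESRD",77280,"0.76"
2032,10217299,"DEATH_CV",2679643,"26.23"
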