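site,treatment,year,average_m,sd_m
Blue Tick,Wide,1996,32.0,13.9
Blue Tick,Wide,2003,36.1,22.1
Eleven 31,Wide,1996,21.9,10.8
Eleven 31,Wide,2003,21.9,10.4
Ms Black,Wide,1996,31.0,10.7
Ms Black,Wide,2003,28.1,9.3
Ryderwood 860,Wide,1996,21.7,5.1
Ryderwood 860,Wide,2003,21.7,5.1
Side Rod,Wide,1996,34.4,14.1
Side Rod,Wide,2003,40.7,24.9
Eleven 32,Narrow,1996,8.8,4.0
Eleven 32,Narrow,2003,6.7,5.2
Kapowsin,Narrow,1996,14.5,4.0
Kapowsin,Narrow,2003,6.7,4.7
Night Dancer,Narrow,1996,10.4,3.8
Night Dancer,Narrow,2003,9.3,5.4
Potpourri,Narrow,1996,25.5,12.1
Potpourri,Narrow,2003,21.3,6.7
Simmons Creek,Narrow,1996,15.6,8.8
Simmons Creek,Narrow,2003,8.7,5.4
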