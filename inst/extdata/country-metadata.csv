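country,locations,period_start,period_end,total_deaths,avg_tmean,tmean_low,tmean_high
Australia,3,1988,2009,1177950,18.1,15.7,20.3
Brazil,18,1997,2011,3401136,24.2,17.7,27.4
Canada,21,1986,2009,2521586,6.5,2.6,10.7
China,15,1996,2008,950130,15.1,7.4,23.7
Italy,11,1987,2010,820390,15.4,12.2,18.4
Japan,47,1985,2012,26893197,15.3,9.1,23.1
South Korea,7,1992,2010,1726938,13.7,12.5,14.9
Spain,51,1990,2010,3479910,15.5,10.9,21.6
Sweden,1,1990,2002,190092,7.5,7.5,7.5
Taiwan,3,1994,2007,765893,24.0,23.2,25.2
Thailand,62,1999,2008,1827853,27.6,25.1,29.3
UK,10,1993,2006,7573716,10.4,9.5,11.7
USA,135,1985,2006,22896409,14.9,7.9,25.5
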