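# Chinese statutory public holidays, 2006-2008 (one ISO date per line).
# New Year, Spring Festival, Labour Day, National Day; Qingming, Dragon
# Boat and Mid-Autumn added by the 2008 holiday reform.
2006-01-01
2006-01-29
2006-01-30
2006-01-31
2006-05-01
2006-05-02
2006-05-03
2006-10-01
2006-10-02
2006-10-03
2007-01-01
2007-02-18
2007-02-19
2007-02-20
2007-05-01
2007-05-02
2007-05-03
2007-10-01
2007-10-02
2007-10-03
2008-01-01
2008-02-06
2008-02-07
2008-02-08
2008-04-04
2008-05-01
2008-06-08
2008-09-14
2008-10-01
2008-10-02
2008-10-03
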