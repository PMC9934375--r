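axis,level,n_all,n_with_food,pct_with_food
size_class,small,149,148,99.3
size_class,large,144,140,97.2
area,within_SCB,203,199,98.0
area,beyond_SCB,96,93,96.9
season_year,2007,48,47,97.9
season_year,2008,17,16,94.1
season_year,2009,38,37,97.4
season_year,2010,12,12,100
season_year,2011,56,54,96.4
season_year,2012,37,36,97.3
season_year,2013,57,56,98.2
season_year,2014,34,34,100
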