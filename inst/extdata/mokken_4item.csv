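# Worked-example ordered joint cumulative probability grid for an
# artificial 4-item, 3-category (scores 0,1,2) assessment. Rows/columns are
# (item, level) pairs ordered ascending by marginal cumulative probability;
# NA marks unobservable same-item cells. The source prints the (row 1,
# column 2) cell as -0.2; its mirror cell is 0.2 and joint cumulative
# probabilities are non-negative, so 0.2 is used here (presumed typo).
item,level,marginal,c1,c2,c3,c4,c5,c6,c7,c8
4,2,0.2,NA,0.2,0.2,0.2,NA,0.2,0.2,0.2
3,2,0.3,0.2,NA,0.3,0.3,0.3,NA,0.3,0.3
2,2,0.4,0.2,0.3,NA,0.4,0.4,0.4,NA,0.4
1,2,0.5,0.2,0.3,0.4,NA,0.5,0.5,0.5,NA
4,1,0.6,NA,0.3,0.4,0.5,NA,0.6,0.6,0.6
3,1,0.7,0.2,NA,0.4,0.5,0.6,NA,0.7,0.7
2,1,0.8,0.2,0.3,NA,0.5,0.6,0.7,NA,0.8
1,1,0.9,0.2,0.3,0.4,NA,0.6,0.7,0.8,NA
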