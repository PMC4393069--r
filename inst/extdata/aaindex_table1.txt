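H PRAM900101
D Hydrophobicity (Prabhakaran, 1990)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      -6.7    51.5    20.1    38.5    -8.4    17.2    34.3    -4.2    12.6     -13
     -11.7    36.8   -14.2   -15.5     0.8    -2.5      -5    -7.9     2.9   -10.9
//
H GRAR740102
D Polarity (Grantham, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
       8.1    10.5    11.6      13     5.5    10.5    12.3       9    10.4     5.2
       4.9    11.3     5.7     5.2       8     9.2     8.6     5.4     6.2     5.9
//
H ZIMJ680102
D Bulkiness (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      11.5   14.28   12.82   11.68   13.46   14.45   13.57     3.4   13.69    21.4
      21.4   15.71   16.25    19.8   17.43    9.47   15.77   21.67   18.03   21.57
//
H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
       1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
       3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H RADA880106
D Accessible surface area (Radzicka-Wolfenden, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      93.7   250.4   146.3   142.6   135.2   177.7   182.9    52.6   188.1   182.2
     173.7   215.2   197.6   228.6       0   109.5   142.1   271.6   239.9   157.2
//
H CHOC760101
D Residue accessible surface area in tripeptide (Chothia, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
       115     225     160     150     135     180     190      75     195     175
       170     200     185     210     145     115     140     255     230     155
//
H JANJ780102
D Percentage of buried residues (Janin et al., 1978)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
        51       5      22      19      74      16      16      52      34      66
        60       3      52      58      25      35      30      49      24      64
//
H HUTJ700103
D Entropy of formation (Hutchens, 1970)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     154.3     341   207.9   194.9   219.8   235.5   223.2   127.9   242.5   233.2
     232.3   300.5   202.7   204.7   179.9   174.1   205.8     237   229.2   207.6
//
H KRIW790103
D Side chain volume (Krigbaum-Komoriya, 1979)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      27.5     105    58.7      40    44.6    80.7      62       0      79    93.5
      93.5     100    94.1   115.5    41.9    29.3    51.3   145.5   117.3    71.5
//
H TAKK010101
D Side-chain contribution to protein stability (kJ/mol) (Takano-Yutani, 2001)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
       9.8     7.3     3.6     4.9       3     2.4     4.4       0    11.9    17.2
        17    10.5    11.9      23      15     2.6     6.9    24.2    17.2    15.3
//
H ZHOH040103
D Buriability (Zhou-Zhou, 2004)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      13.4     8.5     7.6     8.2    22.6     8.5     7.3       7    11.3    20.3
      20.8     6.1    15.7    23.9     9.9     8.2    10.3    24.5    19.5    19.5
//
H HOPT810101
D Hydrophilicity value (Hopp-Woods, 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      -0.5       3     0.2       3      -1     0.2       3       0    -0.5    -1.8
      -1.8       3    -1.3    -2.5       0     0.3    -0.4    -3.4    -2.3    -1.5
//
H FASG760101
D Molecular weight (Fasman, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     89.09   174.2   132.1   133.1   121.2   146.2   147.1   75.07   155.2   131.2
     131.2   146.2   149.2   165.2   115.1   105.1   119.1   204.2   181.2   117.2
//
H BULH740101
D Transfer free energy to surface (Bull-Breese, 1974)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      -0.2   -0.12    0.08    -0.2   -0.45    0.16    -0.3       0   -0.12   -2.26
     -2.46   -0.35   -1.47   -2.33   -0.98   -0.39   -0.52   -2.01   -2.24   -1.56
//
H CHAM810101
D Steric parameter (Charton, 1981)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
      0.52    0.68    0.76    0.76    0.62    0.68    0.68       0     0.7    1.02
      0.98    0.68    0.78     0.7    0.36    0.53     0.5     0.7     0.7    0.76
//
H ZIMJ680104
D Isoelectric point (Zimmerman et al., 1968)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
         6   10.76    5.41    2.77    5.05    5.65    3.22    5.97    7.59    6.02
      5.98    9.74    5.74    5.48     6.3    5.68    5.66    5.89    5.66    5.96
//
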