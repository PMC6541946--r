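# RR interval (s)  pulse pressure (mmHg)
0.5039859604 135.3676205
0.6057673538 182.8894756
0.7428697963 182.6436997
0.6544498464 193.8337301
0.5836733947 148.8523533
0.6898615378 189.0326904
0.7921167637 192.3001636
0.8920678113 185.9366329
0.8038866874 198.5026373
0.6791677402 165.3671584
0.6744965826 199.0569855
0.6630603426 183.356334
0.6029832823 199.2147964
0.7679963723 199.7632898
0.7323294506 199.3514142
0.5800311752 173.9388749
0.5510261474 159.04319
0.7205986214 201.4166921
0.570354846 161.2997591
0.7346040812 169.1749664
0.6547567931 159.9411163
0.5429512155 174.5683298
0.7001405728 178.5921917
0.860556597 217.2875695
0.6237735402 178.1027707
0.693987704 188.8675207
0.7570425416 203.121398
0.839747479 226.3284499
0.775837175 209.4697328
0.8134119432 197.8066274
0.5187436249 166.0316106
0.5590258375 179.2662356
0.8143749952 209.2145588
0.7025427709 186.4905007
0.7920831573 194.0466491
0.7838743967 203.7994653
0.563916933 154.714369
0.7400475525 189.1794855
0.7715797382 198.4571843
0.834624554 174.1962361
0.6908160624 183.8568051
0.8876203469 211.0446817
0.6025979129 190.608684
0.7492220453 209.8726067
0.5570157645 164.9092701
0.6439086718 174.7985479
0.7743564126 199.907034
0.5511301735 167.8436072
0.6980432394 221.4463414
0.7678822533 188.9960988
0.6922864573 208.7883037
0.6307967855 183.3029402
0.7204371089 205.9722547
0.7800495809 209.1811045
0.557884813 146.9823349
0.6150457664 181.6690589
0.6037566766 197.0470093
0.6167916844 178.6663121
0.5930635008 168.0314771
0.7629234956 184.226175
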