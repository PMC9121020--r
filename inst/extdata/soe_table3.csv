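# Published single-omission experiment table: 37 omissions x 2 strains.
# Rows 1-3 are whole-group omissions (is_group TRUE); `component` maps the
# omitted nutrient to its name in cdm.tsv. Row 36 is printed as
# "Thiamine (T)" but sits among the nucleotide bases between uracil and
# xanthine; it is taken to be thymidine (the thymidine row of the medium
# table), hence component = Thymidine.
s_no,omitted,component,is_group,od_0h_zj614,od_24h_zj614,relative_growth_zj614,call_zj614,od_0h_zj625,od_24h_zj625,relative_growth_zj625,call_zj625
1,Amino acids (AA),,TRUE,0.071,0.084,2.0,essential,0.066,0.045,0.95,essential
2,Vitamins (Vit),,TRUE,0.097,0.837,20.17,essential,0.050,2.034,42.7,stimulatory
3,Nucleotide bases (NB),,TRUE,0.098,2.50,60.24,stimulatory,0.055,3.35,70.5,stimulatory
4,L-Alanine (Ala),L-Alanine,FALSE,0.099,4.86,110.20,non_essential,0.073,0.475,9.58,essential
5,L-Isoleucine (Ile),L-Isoleucine,FALSE,0.098,0.421,9.55,essential,0.056,0.517,10.42,essential
6,L-Arginine (Arg),L-Arginine,FALSE,0.095,0.16,3.63,essential,0.07,0.106,2.14,essential
7,DL-Methionine (Met),DL-Methionine,FALSE,0.091,1.56,35.37,essential,0.076,1.93,38.91,essential
8,L-Valine (Val),L-Valine,FALSE,0.083,1.48,33.56,essential,0.063,5.22,105.24,non_essential
9,L-Glutamine (Gln),L-Glutamine,FALSE,0.081,0.083,1.88,essential,0.069,0.139,2.80,essential
10,L-Asparagine (Asn),L-Asparagine,FALSE,0.093,0.072,1.63,essential,0.047,0.129,2.60,essential
11,L-Leucine (Leu),L-Leucine,FALSE,0.117,0.144,3.27,essential,0.042,0.181,3.65,essential
12,L-Glutamic acid (Glu),L-Glutamic acid,FALSE,0.072,0.114,2.59,essential,0.061,0.066,1.33,essential
13,L-Lysine (Lys),L-Lysine,FALSE,0.07,4.12,93.42,non_essential,0.086,4.69,94.56,non_essential
14,L-Threonine (Thr),L-Threonine,FALSE,0.06,0.046,1.04,essential,0.053,0.063,1.27,essential
15,L-Phenylalanine (Phe),L-Phenylalanine,FALSE,0.063,0.264,5.99,essential,0.058,3.06,61.69,stimulatory
16,Glycine (Gly),Glycine,FALSE,0.08,2.775,62.93,stimulatory,0.065,0.882,17.78,essential
17,L-Proline (Pro),L-Proline,FALSE,0.072,4.14,93.88,non_essential,0.041,4.51,90.93,non_essential
18,L-Histidine (His),L-Histidine,FALSE,0.049,0.685,15.53,essential,0.078,0.61,12.30,essential
19,L-Tyrosine (Tyr),L-Tyrosine,FALSE,0.106,0.118,2.68,essential,0.051,2.11,42.54,stimulatory
20,L-Serine (Ser),L-Serine,FALSE,0.065,0.82,18.59,essential,0.043,0.6,12.10,essential
21,L-Cysteine (Cys),L-Cysteine,FALSE,0.065,4.76,107.94,non_essential,0.071,5.27,106.25,non_essential
22,L-Aspartic acid (Asp),L-Aspartic acid,FALSE,0.105,4.78,108.39,non_essential,0.04,4.73,95.36,non_essential
23,L-Tryptophan (Trp),L-Tryptophan,FALSE,0.101,0.581,13.17,essential,0.043,0.732,14.76,essential
24,Pantothenic acid,Pantothenic acid,FALSE,0.042,2.33,52.83,stimulatory,0.05,1.06,21.37,essential
25,Biotin,Biotin,FALSE,0.095,4.13,93.65,non_essential,0.063,5.13,103.43,non_essential
26,Cyanocobalamin,Cyanocobalamin,FALSE,0.082,2.78,63.04,stimulatory,0.076,3.61,72.78,stimulatory
27,Folic acid,Folic acid,FALSE,0.089,3.66,82.99,non_essential,0.067,5.6,112.90,non_essential
28,Pyridoxal,Pyridoxal,FALSE,0.091,2.5,56.69,stimulatory,0.059,1.73,34.88,essential
29,Nicotinic acid,Nicotinic acid,FALSE,0.121,4.81,109.07,non_essential,0.06,5.29,106.65,non_essential
30,PABA,P-Aminobenzoic acid,FALSE,0.125,3.61,81.86,non_essential,0.046,5.57,112.30,non_essential
31,Thiamine HCl,Thiamine HCl,FALSE,0.078,4.09,92.74,non_essential,0.104,4.75,95.77,non_essential
32,Riboflavin,Riboflavin,FALSE,0.093,0.687,15.58,essential,0.041,3.54,71.37,stimulatory
33,Guanine (G),Guanine,FALSE,0.095,4.45,100.91,non_essential,0.064,3.05,61.49,stimulatory
34,Adenine (A),Adenine,FALSE,0.089,3.66,82.99,non_essential,0.066,5.91,119.15,non_essential
35,Uracil (U),Uracil,FALSE,0.063,0.955,21.66,essential,0.101,0.131,2.64,essential
36,Thiamine (T),Thymidine,FALSE,0.098,3.72,84.35,non_essential,0.06,3.94,79.44,stimulatory
37,Xanthine (X),Xanthine,FALSE,0.079,3.5,79.37,stimulatory,0.069,5.16,104.03,non_essential
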