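chr1	24960000	24963500	At1g66960	non_clustered
chr1	29530000	29533500	At1g78500	non_clustered
chr1	29683000	29685500	At1g78950	non_clustered
chr1	29686000	29688500	At1g78955	non_clustered
chr1	29689000	29691500	At1g78960	non_clustered
chr1	29692500	29695000	At1g78970	non_clustered
chr2	2900000	2906000	At2g07050	non_clustered
chr3	16550000	16553500	At3g45130	non_clustered
chr4	8760000	8762500	At4g15340	clustered
chr4	8773000	8776000	At4g15370	clustered
chr5	14250000	14253500	At5g36150	clustered
chr5	17050000	17053500	At5g42600	clustered
chr5	19450000	19453000	At5g48010	clustered
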