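0
4
1.99425018
1.99348427
1.99271837
1.99195247
1.99118657
1.99042067
1.98965476
1.98888886
2.56767311
2.56650491
2.56533671
2.56416851
2.56300031
2.56183211
2.56066391
2.55949572
2.13817280
2.24732063
2.31469942
2.35314839
2.37177219
2.37700856
2.37339249
2.36410304
2.71294540
3.24992374
3.58387109
3.77719638
3.87415544
3.90604084
3.89489634
3.85617462
2.29524125
2.29482483
2.29440841
2.29399200
2.29357558
2.29315917
2.29274275
2.29232634
2.85678670
3.21814607
3.44285272
3.57291182
3.63811034
3.65951016
3.65194814
3.62582490
2.42008384
2.41932113
2.41855842
2.41779571
2.41703299
2.41627028
2.41550757
2.41474486
2.99862155
3.33883688
3.54993788
3.67161250
3.73200455
3.75101403
3.74265933
3.71676734
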