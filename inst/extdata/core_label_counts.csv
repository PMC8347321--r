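cyp,substrates_without_hunt,substrates,nonsubstrates_without_hunt,nonsubstrates
1A2,280,296,1441,1428
2A6,107,107,1607,1607
2B6,150,150,1561,1561
2C8,140,149,1572,1565
2C9,237,253,1484,1469
2C19,225,242,1493,1481
2D6,276,304,1441,1425
2E1,148,156,1566,1556
3A4,478,520,1241,1239
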