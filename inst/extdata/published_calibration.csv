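sample,glucose_kit,intensity_whole_blood,sd_whole_blood,glucose_chip_whole_blood,intensity_plasma,sd_plasma,glucose_chip_plasma
1,50,140.3,12.7,48.9,160.3,14.0,50.6
2,71,159.3,2.1,76.8,158.0,3.8,47.0
3,87,148.7,1.5,61.2,165.0,3.0,57.7
4,88,158.3,1.5,75.4,187.3,5.0,91.9
5,128,174.3,8.1,98.9,167.0,2.1,60.8
6,72.48,179.3,11.2,106.2,175.0,15.4,73.0
7,74.31,183.7,8.4,112.6,182.3,5.9,84.2
8,135,192.7,2.5,125.8,193.0,2.5,100.5
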