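country,n
Belgium,2750
Bulgaria,2682
Chile,4753
Colombia,4992
Denmark,5692
Germany,1313
Dominican Republic,2779
Estonia,2770
Finland,3037
Hong Kong,2553
Croatia,3655
Italy,3274
Republic of Korea,2557
Lithuania,3422
Latvia,3000
Mexico,4987
Malta,3317
Netherlands,2692
Norway,5740
Peru,4713
Russia,7049
Slovenia,2664
Sweden,2828
Taiwan,3904
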