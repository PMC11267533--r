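      Assignment         w1         w2
           A1N-H   112.8999     9.0006
           G2N-H   125.8772     9.0767
           P3N-H   113.5581     7.0780
           R4N-H   122.2865     9.6838
           N5N-H   113.8160     7.5595
           E6N-H   106.5086     7.8350
           S7N-H   127.0836     9.5057
           F8N-H   115.1296     8.5157
           N9N-H   105.3884     8.2733
          C10N-H   108.1086     8.1193
          W11N-H   108.4840     7.2990
          R12N-H   122.5310     8.7640
          Q13N-H   120.6113     8.3018
          T14N-H   110.5134     8.6004
          N15N-H   120.1321     8.8562
          L16N-H   114.8372     9.4593
          V17N-H   128.2907     8.1295
          C18N-H   106.1444     9.0290
          F19N-H   112.3372     9.3997
          N20N-H   107.8647     7.5194
          F21N-H   104.4961     8.7686
          S22N-H   119.2985     8.9772
          D23N-H   107.1256     8.5164
          N24N-H   107.6127     7.5743
          D25N-H   125.5912     9.5185
          D26N-H   115.8801     7.3456
          L27N-H   106.8071     9.6638
          E28N-H   119.4207     9.1911
          I29N-H   125.4425     9.6986
          V30N-H   115.2186     7.3178
          C31N-H   104.7781     9.7410
          P32N-H   114.1693     8.7416
          K33N-H   116.4010     9.5973
          N34N-H   104.2090     7.5681
          F35N-H   114.9070     7.6000
          K36N-H   114.3812     9.5823
          P37N-H   121.6344     9.0208
          V38N-H   104.0360     9.1324
          K39N-H   105.6911     7.7999
          S40N-H   128.3867     7.9643
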