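      Assignment         w1         w2
           A1N-H   112.9004     9.0046
           G2N-H   125.8508     9.0738
           P3N-H   113.5705     7.1285
           R4N-H   122.2886     9.6818
           N5N-H   113.8115     7.5632
           E6N-H   106.5096     7.8356
           S7N-H   127.0945     9.5076
           F8N-H   115.1312     8.5850
           N9N-H   105.3789     8.2754
          C10N-H   108.1048     8.1185
          W11N-H   108.2479     7.2324
          R12N-H   122.5294     8.7650
          Q13N-H   120.6029     8.3023
          T14N-H   110.5263     8.6027
          N15N-H   120.1205     8.8542
          L16N-H   114.8463     9.4581
          V17N-H   128.1264     8.0610
          C18N-H   106.1367     9.0260
          F19N-H   112.3348     9.4020
          N20N-H   107.8803     7.5215
          F21N-H   104.4958     8.7716
          S22N-H   119.0452     9.0107
          D23N-H   107.1157     8.5171
          N24N-H   107.6077     7.5732
          D25N-H   125.5855     9.5200
          D26N-H   115.8687     7.3460
          L27N-H   106.8142     9.6643
          E28N-H   119.4269     9.1888
          I29N-H   125.4426     9.6940
          V30N-H   115.2152     7.3199
          C31N-H   104.7641     9.7371
          P32N-H   114.1779     8.7373
          K33N-H   116.4097     9.5968
          N34N-H   104.2013     7.5663
          F35N-H   114.9110     7.6035
          K36N-H   114.3834     9.5814
          P37N-H   121.6283     9.0219
          V38N-H   104.0421     9.1328
          K39N-H   105.6983     7.7988
          S40N-H   128.3893     7.9622
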