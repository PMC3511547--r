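22 rs001 16050000 A G     0.0245      0.971     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045     0.0245      0.971     0.0045
22 rs002 16075000 C T     0.9745      0.021     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045
22 rs003 16100000 G A     0.0245      0.971     0.0045     0.0245      0.971     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045
22 rs004 16125000 T C     0.0245      0.021     0.9545     0.0245      0.971     0.0045     0.9745      0.021     0.0045     0.0245      0.971     0.0045
22 rs005 16150000 A G     0.0245      0.971     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045
22 rs006 16175000 C T     0.0245      0.021     0.9545     0.0245      0.971     0.0045     0.9745      0.021     0.0045     0.9745      0.021     0.0045
22 rs007 16200000 G A     0.0245      0.971     0.0045     0.0245      0.971     0.0045     0.0245      0.971     0.0045     0.0245      0.971     0.0045
22 rs008 16225000 T C     0.9745      0.021     0.0045     0.0245      0.971     0.0045     0.0245      0.971     0.0045     0.0245      0.021     0.9545
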