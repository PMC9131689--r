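# cell-based interventions
stem cell
stem cells
mesenchymal stromal cells
mesenchymal stem cells
bone marrow derived cells
cell transplantation
autologous cell therapy
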