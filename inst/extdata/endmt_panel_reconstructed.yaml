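# Endothelial-to-mesenchymal transition (EndMT) marker panel.
# RECONSTRUCTED panel: assembled from the EndMT genes named in the reference
# analysis (Icam1, Vcam1, Vim, Fn1, Smtn) plus canonical early (transcription
# factor) and late (mesenchymal product) EndMT markers; the original
# supplementary panel is not redistributed here.
panel:
  - {gene: Snai1, phase: early}
  - {gene: Snai2, phase: early}
  - {gene: Twist1, phase: early}
  - {gene: Zeb1, phase: early}
  - {gene: Zeb2, phase: early}
  - {gene: Cdh2, phase: early}
  - {gene: Icam1, phase: late}
  - {gene: Vcam1, phase: late}
  - {gene: Vim, phase: late}
  - {gene: Fn1, phase: late}
  - {gene: Smtn, phase: late}
  - {gene: S100a4, phase: late}
  - {gene: Acta2, phase: late}
  - {gene: Tagln, phase: late}
  - {gene: Col1a1, phase: late}
  - {gene: Col3a1, phase: late}
  - {gene: Serpine1, phase: late}
  - {gene: Postn, phase: late}
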