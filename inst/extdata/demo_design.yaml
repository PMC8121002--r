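# Small synthetic-community design (three designed taxa) exercising all
# three screening cases: PHB producible by a single taxon, ectoine only by
# the pooled community, lutein by nobody. Species names are invented.
taxa:
  - name: Sphaerotilus syntheticus
    lineage: Bacteria;Proteobacteria;Gammaproteobacteria;Burkholderiales;Sphaerotilaceae;Sphaerotilus;Sphaerotilus syntheticus
    n_contigs: 4
    background: 20
  - name: Hyphomicrobium fictum
    lineage: Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Hyphomicrobiaceae;Hyphomicrobium;Hyphomicrobium fictum
    n_contigs: 3
    background: 10
  - name: Caldilinea simulata
    lineage: Bacteria;Chloroflexi;Caldilineae;Caldilineales;Caldilineaceae;Caldilinea;Caldilinea simulata
    n_contigs: 3
    background: 15
complements:
  Sphaerotilus syntheticus:
    PHB: complete
    ectoine: {missing: [ectA, ectC]}
  Hyphomicrobium fictum:
    ectoine: {missing: [lysC, asd]}
  Caldilinea simulata:
    acetoin: {missing: [E2.2.1.6S, budC, BDH]}
count_model: {family: uniform, min: 5, max: 40}
unclassified_fraction: 0.1
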