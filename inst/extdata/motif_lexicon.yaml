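# IUPAC consensus motif lexicon for med/end promoter scanning.
# Entries marked "placeholder" stand in for consensus strings that are only
# defined by external motif-discovery output and can be overridden from a
# user lexicon.
motifs:
  - name: skn1_double
    consensus: RTCATCAT
    strands: both
    notes: two overlapping SKN-1 core sites; hallmark of med promoters
  - name: skn1_core
    consensus: RTCAT
    strands: both
    notes: SKN-1 core site
  - name: skn1_degenerate
    consensus: TCATTYTCATC
    strands: both
    notes: degenerate (low-affinity) SKN-1-like site of the end promoters
  - name: skn1_www
    consensus: WWWRTCATC
    strands: both
    notes: extended SKN-1 consensus with AT-rich 5' flank
  - name: med_site
    consensus: AGTATAC
    strands: both
    notes: atypical MED-factor binding core (non-HGATAR GATA site)
  - name: gata_canonical
    consensus: HGATAR
    strands: both
    notes: canonical GATA-factor binding site
  - name: tctkcac
    consensus: TCTKCAC
    strands: both
    notes: uncharacterized motif co-occurring with SKN-1 sites in med promoters
  - name: patc_like
    consensus: TTTNNAAA
    strands: both
    notes: periodic A/T cluster-like motif
  - name: sp1
    consensus: GGGCGG
    strands: both
    notes: placeholder canonical Sp1 hexamer
  - name: tata
    consensus: TATAWAWR
    strands: both
    notes: placeholder TATA-box consensus
  - name: sl1_outron
    consensus: TTTCAG
    strands: top
    notes: placeholder trans-splice acceptor-like element
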