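# Default synthetic cohort: eight populations across the three ecological
# zones. An. gambiae s.s. fixed for the FVI haplotype class; An. coluzzii
# mixing LVI/FVI/LL1T with rare LL2T; An. arabiensis mixing FVI and SVI.
# Gene coordinates below are synthetic placements of real detoxification gene
# identifiers, used only for arm/family bookkeeping.
class_private_sites: 3
annotation:
  - {gene_id: AGAP002863, gene_name: COEAE6O, family: COE, contig: 2R, start: 28548433, end: 28550748}
  - {gene_id: AGAP005835, gene_name: COEJHE5E, family: COE, contig: 2L, start: 24480000, end: 24482400}
  - {gene_id: AGAP009194, gene_name: GSTE2, family: GST, contig: 3R, start: 28597652, end: 28598500}
  - {gene_id: AGAP004173, gene_name: GSTD5, family: GST, contig: 2L, start: 615000, end: 616200}
  - {gene_id: AGAP000818, gene_name: CYP9K1, family: CYP, contig: X, start: 15240572, end: 15242864}
  - {gene_id: AGAP002865, gene_name: CYP6AA1, family: CYP, contig: 2R, start: 28480576, end: 28483070}
  - {gene_id: AGAP008212, gene_name: CYP6M2, family: CYP, contig: 3R, start: 6928858, end: 6930580}
  - {gene_id: AGAP012296, gene_name: CYP12F2, family: CYP, contig: 3L, start: 4001734, end: 4003600}
populations:
  - name: Bana
    species: An_coluzzii
    site: Bana
    zone: Sudanian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.33, FVI: 0.32, LL1T: 0.32, LL2T: 0.03}
    cn_specs:
      AGAP002863: {amp_freq: 0.80, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.60}
      AGAP000818: {amp_freq: 0.70, del_freq: 0.00}
      AGAP002865: {amp_freq: 0.40, del_freq: 0.00}
      AGAP012296: {amp_freq: 0.00, del_freq: 0.70}
  - name: Souroukoudinga
    species: An_coluzzii
    site: Souroukoudinga
    zone: Sudanian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.36, FVI: 0.28, LL1T: 0.32, LL2T: 0.04}
    cn_specs:
      AGAP002863: {amp_freq: 0.73, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.70}
      AGAP000818: {amp_freq: 0.42, del_freq: 0.00}
      AGAP002865: {amp_freq: 0.30, del_freq: 0.00}
  - name: Sideradougou
    species: An_coluzzii
    site: Sideradougou
    zone: Sudanian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.30, FVI: 0.35, LL1T: 0.33, LL2T: 0.02}
    cn_specs:
      AGAP002863: {amp_freq: 0.40, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.55}
      AGAP008212: {amp_freq: 0.20, del_freq: 0.00}
  - name: Po-Dongo
    species: An_gambiae_ss
    site: Po-Dongo
    zone: Sudanian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {FVI: 1.0}
    cn_specs:
      AGAP000818: {amp_freq: 0.90, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.95}
      AGAP005835: {amp_freq: 0.50, del_freq: 0.00}
  - name: Nagare
    species: An_coluzzii
    site: Nagare
    zone: Sudano_Sahelian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.35, FVI: 0.30, LL1T: 0.33, LL2T: 0.02}
    cn_specs:
      AGAP002863: {amp_freq: 0.30, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.53}
  - name: Gama
    species: An_coluzzii
    site: Gama
    zone: Sudano_Sahelian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.32, FVI: 0.33, LL1T: 0.32, LL2T: 0.03}
    cn_specs:
      AGAP002865: {amp_freq: 0.26, del_freq: 0.00}
      AGAP012296: {amp_freq: 0.00, del_freq: 0.40}
  - name: Nassan
    species: An_arabiensis
    site: Nassan
    zone: Sudano_Sahelian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {FVI: 0.7, SVI: 0.3}
    cn_specs:
      AGAP005835: {amp_freq: 0.64, del_freq: 0.00}
      AGAP004173: {amp_freq: 0.00, del_freq: 0.90}
      AGAP012296: {amp_freq: 0.00, del_freq: 0.68}
  - name: Ouro-Hesso
    species: An_coluzzii
    site: Ouro-Hesso
    zone: Sahelian
    n_samples: 100
    sex_ratio: 0.7
    n_background_sites: 750
    kdr_hap_freqs: {LVI: 0.30, FVI: 0.28, LL1T: 0.39, LL2T: 0.03}
    cn_specs:
      AGAP002863: {amp_freq: 0.26, del_freq: 0.00}
      AGAP000818: {amp_freq: 0.08, del_freq: 0.00}
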