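# tdmdscan pipeline configuration (flat key = value, one per line).
# Values listed here are the package defaults; comma-separated values
# become vectors.  Flags passed to the CLI override these keys.

[synthetic]
rng_seed = 1                      # master seed; all stages derive from it
n_mirnas = 10                     # ZSWIM8-regulated miRNAs in the catalog
n_transcripts = 60                # transcripts (plus contaminant snoRNAs)
transcript_length_range = 500, 1500
chimera_fraction = 0.02           # fraction of reads that are chimeric
enrichment_factor = 8             # probe-capture boost for enriched miRNAs
contaminant_fraction = 0.05       # snoRNA-like contaminant reads
sequencing_error_rate = 0.001     # per-base substitution probability
umi_length = 10
adapter_sequence = AGATCGGAAGAGC
reads_total = 200000
site_chimera_bias = 0.8           # chimeras drawn from embedded sites
n_contaminants = 4

[process]
umi_length = 10
adapter = AGATCGGAAGAGC
adapter_min_overlap = 3
adapter_max_mismatch_rate = 0.1
contaminant_max_mismatches = 1
mirna_max_mismatches = 1
min_mirna_match = 16
target_max_mismatches = 2
min_target_len = 15
contaminant_regex = ^Snord

[filter]
max_central_unpaired_run = 7      # central-bulge criterion (nt)
min_three_prime_run = 6           # consecutive 3' pairs criterion (bp)
three_prime_region_len = 13       # miRNA 3' region = final 13 nt
flank_len = 20                    # target flank 5' of the seed window
top_k = 3                         # candidates selected per miRNA
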