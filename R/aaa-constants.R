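# package-wide constants (file sorts first in collation order)

BIOTYPES <- c("miRNA", "lncRNA", "mRNA")

# canonical biotype precedence used for edge ordering
BIOTYPE_RANK <- stats::setNames(seq_along(BIOTYPES), BIOTYPES)

CLASS_LABELS <- c("tissue_specific", "nonspecific", "intermediate")
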