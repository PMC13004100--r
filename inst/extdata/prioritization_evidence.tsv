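# Functional-evidence table for the 18 credible-set variants, recoded from
# the published prioritization evidence.  regulatory_overlap counts only
# narrow-peak-supported overlap; overlap seen only in gapped peaks is
# recorded in gapped_peak_only and does not count toward the criteria.
# increases_expression is FALSE throughout because every non-coding variant
# was associated with *reduced* transcript/protein levels; qtl_colocalizes
# is FALSE (no eQTL/pQTL colocalization was observed).  The single coding
# non-synonymous variant carries 7 deleterious votes from 9 predictors.
variant_id	is_coding_nonsynonymous	regulatory_overlap	gapped_peak_only	re2g_link	increases_expression	qtl_colocalizes	deleterious_votes	total_predictors
rs1801690	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	7	9
rs9902706	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	NA	NA
rs9906486	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs9905408	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs7211380	FALSE	FALSE	TRUE	FALSE	FALSE	FALSE	NA	NA
rs74934196	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs74531840	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs76375367	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs55657678	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs11651658	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs73992250	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs7216660	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs9891968	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs9908597	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs9895407	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs77620153	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs73992258	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
rs9911603	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	NA	NA
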