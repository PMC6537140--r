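# Example plate layout: one comparison group of three strains on a 96-well
# plate, three replicate wells per strain, 15 fields of view imaged per
# well (45 FOVs per strain per run).
fovs_per_well: 15
replicate_wells_per_strain: 3
wells:
  A1: {strain: donor_only, group: g1, role: negative_control}
  A2: {strain: donor_only, group: g1, role: negative_control}
  A3: {strain: donor_only, group: g1, role: negative_control}
  B1: {strain: donor_acceptor_pair, group: g1, role: query}
  B2: {strain: donor_acceptor_pair, group: g1, role: query}
  B3: {strain: donor_acceptor_pair, group: g1, role: query}
  C1: {strain: tandem_fusion, group: g1, role: positive_control}
  C2: {strain: tandem_fusion, group: g1, role: positive_control}
  C3: {strain: tandem_fusion, group: g1, role: positive_control}
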