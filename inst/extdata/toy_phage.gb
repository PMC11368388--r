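LOCUS       TOY01                600 bp    DNA     linear   PHG 01-JAN-2024
DEFINITION  toy phage genome for examples
ACCESSION   TOY01
VERSION     TOY01
FEATURES             Location/Qualifiers
     source          1..600
     gene            61..240
                     /locus_tag="toyA"
     CDS             61..240
                     /locus_tag="toyA"
                     /protein_id="TOYP1.1"
                     /product="toy portal protein"
     gene            complement(301..480)
                     /locus_tag="toyB"
                     /gene="terS"
     CDS             complement(301..480)
                     /locus_tag="toyB"
                     /gene="terS"
                     /protein_id="TOYP2.1"
                     /product="toy terminase small subunit"
ORIGIN
        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
       61 atgaaagcca ttgaccttca aggtgaactg gctgaaatcg ttcgtaaagc tgttgctgaa
      121 ggtaaagacg ttgttgctct ggctgctgaa aaagttgctg aactgcaagc tgaaatcgct
      181 cgtctggaag ctgaaaacgc tgctctgaaa gctgctgttg aagctctgaa agctgaataa
      241 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      301 ttattcagct ttcagagctt caacagcagc tttcagagca gcgttttcag cttccagacg
      361 agcgatttca gcttgcagtt cagcaacttt ttcagcagcc agagcaacaa cgtctttacc
      421 ttcagcaaca gctttacgaa cgatttcagc cagttcacct tgaaggtcaa tggctttcat
      481 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
      541 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt
//
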