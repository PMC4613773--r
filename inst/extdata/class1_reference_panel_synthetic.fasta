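>REF01 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQPPSSLHWQQVEKNQDVVERPNALKKQLIWGQIKPHNK
NTQPTEDYQYDHGTQAYLRYSEKRHVKSVSDATSQLLDQTNKYYINARQQIYRGSYTTEEVTQQFVNDTD
WDGGVPAEDNKAVFDSVWAYASEGESGECYTKVLEKESVDSTDHASGVEYTVKPRTAHSTFSIFTYGRFN
LENTTPASLNAEIYDDKQSYGKNTIDFGYEMDNLDSQGSETSVYTFKTIGTYSAVATGAKYHNTPRETDG
NSYPLTEVVSQWVSKQRSDPPKTHVTHHFLIVAILVALMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLT
>REF02 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQYPSSLHWQQVEKNQDVVEAHNALKKQLIWGQIHPHNK
NTQPTEDYQYSHGTQAYLRYSETRHVKSVSDATSQLLDLTNKYYINAGQQIYEGSYTTEEVTQSGVSDTD
WDGGVPAEDNKAVFDSVWRYASEGASGECYTFVLEKEEVDSTDHASGVEYTVKPRTAHDTRSSFTYGRFN
LENETPASLNAEIHDDKISYGKNTIDFGEEMDNLDSQRSETSVYTFKTIGTYSAVATGAKYHNTPREIDG
NSYPLTEVVSQWVSKQRSDPPKTHVTHHFLIVAILVALMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLTAD
>REF03 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQPPSSLRWQQVEKNQDVVEAPNALKDQLIWGQEKPHNK
NTQPTEKYQYSHGTQAYLRYSETRHVKSVSDATSQLLDLTHKYYINAGQQIYTGSYTTEEVTQQFVNGTD
WDGGVPAEDNKAVFDSVWAYASEGASGECYTFVLEKSSVDSTDHASGVEYTVKPRTAHDTFSIFTYGRFN
LENETPASLNAEIHDDKISYDKNTIDFGEEMDNLDSQGSETSVYTFKTIGTYSAVATGAKYHNTPREIDG
NSYPLTEVVSGWVSKQRSDPPKTHVTHHFLIVAILVPIMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLT
>REF04 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQPPSSDHWQKVEKNQTVVEAPNANKKQLIWGQIKPHNK
ETQPSEDYQTSHGTQAYLRYSETRHVKSVSDATSQTLDLTNKYYINAGQQIYTGSYTTEEVTQQFVNDTD
WDTGVPAEDTKAVFDSVWAYASEGASGECYTFVLEGESVGSHDHASGVEYTVKPRTAHDTFSIFTYGRFN
LENETPASLNAEISKDKISYGKNTIDFGEEMDNLDSQGSETSVYTFKTIGTYSAVATGAKYHNTPREIDG
NSYPLTEVVQQWVSKQRSDPPKTHVTHHFLIVAILVALMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLTADKRR
>REF05 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVGPPSSLHWQQVEKNQDVVEAPNALKKQLIWGQIKPHNK
NTQPTEDKQYSHGTYAKLRYSETRHVKGVSDATSQLLDLTNKYYINAGQQIYTGSYTTEEVTQQFVNDTD
WDGGVPAEDNKAVFDHVWAYASQGASGECYTFVLEKEKVDSTDHASGVEYTVKPRTAHDTFSIFTYGRFN
LENETPASLNAEIHDDKISYGKNTIDFGEESDNDDSQGSETSVYTFETIGTYSTVATGAKYHNTPREIDY
NSYPLTEVVSQWVSNQRSDPPKTHVTHHFLIVAILIPIMLIVAFVIALVLLRKSSDRKGGSYS
>REF06 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQPPSSLHWQQVEKNQDVVEAPNALKKQLIWGQIKSHNK
NTQPTEDYQYSHGTQAYLHYSRTRHVKSVSDATSQLLDLTNKYYINAGQQIYTGSYTTEEVTQQFVNDTD
WDGGVPAEDNKAVFDSVWEYASEGASGQCYTFVLEKESNDSTDHASGVEYTVKPRTAHDTFSIFTYGRFN
LEYESPASLNAEIHDDKISEGKNTIDFGKEMDGLDSQGTETSVYTFKTIGTYSAVATGAKYHNTPREIDG
NSYPLTEVVSQWVSEQRSDPPKTHVTHHFLIVAILVALMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLT
>REF07 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHDQAVQPPSSLHWQQVEKNQDVVEAPNALHKQLEWGQIKPHNK
NTQPTEDYQYSHGTQAYLRYSETRHVKSVSDATSQLLDTTNKYYINATQQIYTGSYTTEEVTQQFVYDTD
WDGGVPAEDNKAVFDSVWAYASEGASGRCYTFVLEKESVDSTDHASGQEYTVKPRYAHDTFSIFTYGRFN
LENETPASLNAEITDDKISYGKNTIDFGEEMDNLDSQGSETSVYTFKTIGTESEVATGAKYHNTPREIDG
NSYPLTEVVSQWVSKQRSDPPKTHVTHHFLIVAILVLIKLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVSLTAD
>REF08 synthetic class I protein
MAVMAPRTLLLLLSGALALTQTWARESHIQAVQPPSSHHWQQVEKNQDVVEAPNALKKQLIWGQIKPHNK
NTQPTEDQQYSHRTQAYLRYSETRHVKRVSDATSQLLDTTNKYYINAGQQEYTGSYTREEVTQQFVNDTD
WDGGVPAEDNKAVFDDVWAYASEGASGECKTFVLEKESVDSTDHASGVEYTVKPRTAHDTFSIFTYGRFN
LENETPASLNAEIHDDKISYGKNTIDFGEEMDNLDSQGSETSVYTFKTIGTYNAVATGAKYHNTPREIDG
NHYPLTQVVSQWVSKQRSDPPKTHVTHHFLIVAILVALMLIVAFVIALVLLRKSSDRKGGSYSQAASNDS
AQGSDVS
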