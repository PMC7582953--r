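# Synthetic NMR-STAR 3.1 example built against the heteronuclear
# relaxation saveframe layout of the BMRB dictionary.  All values are
# simulated; this is not deposited data.
data_synthetic_relaxation

save_heteronucl_T1_list_1
   _Heteronucl_T1_list.Sf_category                    heteronucl_T1_relaxation
   _Heteronucl_T1_list.ID                             1
   _Heteronucl_T1_list.Spectrometer_frequency_1H      800.13
   _Heteronucl_T1_list.T1_coherence_type              Nz
   _Heteronucl_T1_list.T1_val_units                   s-1

   loop_
      _T1.ID
      _T1.Comp_index_ID
      _T1.Comp_ID
      _T1.Val
      _T1.Val_err

      1   2   CYS   1.62   0.05
      2   3   THR   1.58   0.04
      3   4   LEU   1.65   0.05
   stop_
save_

save_heteronucl_T2_list_1
   _Heteronucl_T2_list.Sf_category                    heteronucl_T2_relaxation
   _Heteronucl_T2_list.ID                             1
   _Heteronucl_T2_list.Spectrometer_frequency_1H      800.13
   _Heteronucl_T2_list.T2_coherence_type              Nxy
   _Heteronucl_T2_list.T2_val_units                   s-1

   loop_
      _T2.ID
      _T2.Comp_index_ID
      _T2.Comp_ID
      _T2.Val
      _T2.Val_err

      1   2   CYS   8.90   0.27
      2   3   THR   9.10   0.28
      3   4   LEU   8.75   0.26
   stop_
save_

save_heteronucl_NOE_list_1
   _Heteronucl_NOE_list.Sf_category                   heteronucl_NOEs
   _Heteronucl_NOE_list.ID                            1
   _Heteronucl_NOE_list.Spectrometer_frequency_1H     800.13

   loop_
      _Heteronucl_NOE.ID
      _Heteronucl_NOE.Comp_index_ID
      _Heteronucl_NOE.Comp_ID
      _Heteronucl_NOE.Val
      _Heteronucl_NOE.Val_err

      1   2   CYS   0.82   0.02
      2   3   THR   0.80   0.02
      3   4   LEU   .     .
   stop_
save_
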