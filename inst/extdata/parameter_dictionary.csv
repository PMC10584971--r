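block,name,label,units
fresh,oocyte_pickup,Oocyte pick up,pct
fresh,usable_oocytes,Oocytes after pick up,pct
fresh,icsi_share,IVF versus ICSI (probability of ICSI),pct
fresh,ivf_fertilization,Fertilization after IVF,pct
fresh,ivf_transfer,Embryo transfer after IVF fertilization,pct
fresh,ivf_pregnancy,Pregnancy after IVF embryo transfer,pct
fresh,icsi_fertilization,Fertilization after ICSI,pct
fresh,icsi_transfer,Embryo transfer after ICSI fertilization,pct
fresh,icsi_pregnancy,Pregnancy after ICSI embryo transfer,pct
frozen,embryo_survival,Survival frozen embryo,pct
frozen,pregnancy_after_survival,Clinical pregnancy after survived embryo,pct
sequence,start_cycle2_after_failure,Initiating 2nd cycle after failure of 1st cycle,pct
sequence,fresh_share_cycle2,Fresh cycle at 2nd cycle versus frozen cycle,pct
sequence,start_cycle3_after_failure,Initiating 3rd cycle after failure of 2nd cycle,pct
sequence,fresh_share_cycle3,Fresh cycle at 3rd cycle versus frozen cycle,pct
cost,stim_rfsh,rFSH stimulation treatment,eur
cost,stim_rfsh_myoins,rFSH + inositol stimulation treatment,eur
cost,other_hormones,"Other hormones (GnRHa, hCG)",eur
cost,monitoring_ultrasounds,Monitoring ultrasounds,eur
cost,consultations,Consultations,eur
cost,oocyte_pickup,Oocyte pickup,eur
cost,pickup_ultrasound,Ultrasound at oocyte pickup,eur
cost,ivf_lab,IVF laboratory,eur
cost,fresh_et_ivf_catheter,Fresh embryo transfer after IVF: catheter + disposables,eur
cost,ohss_treatment,OHSS treatment,eur
cost,icsi_procedure,ICSI,eur
cost,icsi_lab,ICSI laboratory,eur
cost,icsi_et_catheter,Embryo transfer after ICSI: catheter + disposables,eur
cost,freeze_and_thaw,Frozen embryo and thawing,eur
cost,frozen_et_catheter,Frozen embryo transfer: catheter + disposables,eur
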