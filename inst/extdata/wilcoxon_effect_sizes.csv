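comparison,region,metric,method,z,r
wm_error,whole_brain_wm,average,phm,3.73,0.59
wm_error,whole_brain_wm,average,nhm,3.36,0.53
wm_error,whole_brain_wm,average,chm,3.92,0.62
wm_error,whole_brain_wm,average,rls,0.82,0.13
wm_error,whole_brain_wm,average,sps,3.88,0.61
wm_error,whole_brain_wm,average,t1map,3.10,0.49
wm_error,wm_roi,average,phm,2.46,0.39
wm_error,wm_roi,average,nhm,2.80,0.44
wm_error,wm_roi,average,chm,1.57,0.25
wm_error,wm_roi,average,rls,3.14,0.50
wm_error,wm_roi,average,sps,3.10,0.49
wm_error,wm_roi,average,t1map,3.62,0.57
wm_error,whole_brain_wm,maximum,phm,3.81,0.60
wm_error,whole_brain_wm,maximum,nhm,3.77,0.60
wm_error,whole_brain_wm,maximum,chm,3.92,0.62
wm_error,whole_brain_wm,maximum,rls,2.50,0.40
wm_error,whole_brain_wm,maximum,sps,3.88,0.61
wm_error,whole_brain_wm,maximum,t1map,1.75,0.28
wm_error,wm_roi,maximum,phm,1.64,0.26
wm_error,wm_roi,maximum,nhm,2.35,0.37
wm_error,wm_roi,maximum,chm,-0.16,-0.03
wm_error,wm_roi,maximum,rls,3.14,0.50
wm_error,wm_roi,maximum,sps,2.95,0.47
wm_error,wm_roi,maximum,t1map,0.60,0.09
gm_error,whole_brain_gm,average,phm,-3.21,-0.51
gm_error,whole_brain_gm,average,nhm,-3.62,-0.57
gm_error,whole_brain_gm,average,chm,3.66,0.58
gm_error,whole_brain_gm,average,rls,0.47,0.07
gm_error,whole_brain_gm,average,sps,3.78,0.60
gm_error,whole_brain_gm,average,t1map,0.11,0.02
gm_error,gm_roi,average,phm,-2.58,-0.41
gm_error,gm_roi,average,nhm,-2.69,-0.43
gm_error,gm_roi,average,chm,0.97,0.15
gm_error,gm_roi,average,rls,3.81,0.60
gm_error,gm_roi,average,sps,3.06,0.48
gm_error,gm_roi,average,t1map,0.37,0.06
gm_error,whole_brain_gm,maximum,phm,-3.55,-0.56
gm_error,whole_brain_gm,maximum,nhm,-3.66,-0.58
gm_error,whole_brain_gm,maximum,chm,3.58,0.57
gm_error,whole_brain_gm,maximum,rls,-1.74,-0.27
gm_error,whole_brain_gm,maximum,sps,3.81,0.60
gm_error,whole_brain_gm,maximum,t1map,1.01,0.16
gm_error,gm_roi,maximum,phm,-2.50,-0.40
gm_error,gm_roi,maximum,nhm,-2.43,-0.38
gm_error,gm_roi,maximum,chm,0.49,0.08
gm_error,gm_roi,maximum,rls,3.73,0.59
gm_error,gm_roi,maximum,sps,3.19,0.50
gm_error,gm_roi,maximum,t1map,-0.82,-0.13
intensity_difference,whole_brain_wm,mean_abs,phm,3.88,0.61
intensity_difference,whole_brain_wm,mean_abs,nhm,3.85,0.61
intensity_difference,whole_brain_wm,mean_abs,chm,3.92,0.62
intensity_difference,whole_brain_wm,mean_abs,rls,3.85,0.61
intensity_difference,whole_brain_wm,mean_abs,sps,3.73,0.59
intensity_difference,wm_roi,mean_abs,phm,3.92,0.62
intensity_difference,wm_roi,mean_abs,nhm,3.92,0.62
intensity_difference,wm_roi,mean_abs,chm,3.14,0.50
intensity_difference,wm_roi,mean_abs,rls,3.92,0.62
intensity_difference,wm_roi,mean_abs,sps,3.10,0.49
intensity_difference,whole_brain_gm,mean_abs,phm,-2.02,-0.32
intensity_difference,whole_brain_gm,mean_abs,nhm,-2.17,-0.34
intensity_difference,whole_brain_gm,mean_abs,chm,0.07,0.01
intensity_difference,whole_brain_gm,mean_abs,rls,3.66,0.58
intensity_difference,whole_brain_gm,mean_abs,sps,3.47,0.55
intensity_difference,gm_roi,mean_abs,phm,-1.05,-0.17
intensity_difference,gm_roi,mean_abs,nhm,-0.34,-0.05
intensity_difference,gm_roi,mean_abs,chm,0.60,0.09
intensity_difference,gm_roi,mean_abs,rls,3.92,0.62
intensity_difference,gm_roi,mean_abs,sps,3.66,0.58
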